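#' Growth model specifications
#'
#' The package fits a nested family of sigmoidal growth models. All four are
#' special cases of the Baranyi-Roberts model
#' \deqn{N(t) = K / \left[1 + ((K/N_0)^v - 1)\, e^{-r v A(t)}\right]^{1/v}}
#' where \eqn{A(t)} is the integral of the physiological adjustment function
#' \eqn{\alpha(t) = q_0/(q_0 + e^{-m t})}. Fixing \eqn{v = 1} gives logistic
#' saturation; dropping the lag machinery (\eqn{q_0, m \to \infty}, i.e.
#' \eqn{\alpha \equiv 1}) gives the no-lag members:
#'
#' \describe{
#'   \item{Logistic}{\eqn{v = 1}, no lag; free \eqn{N_0, r, K} (k = 3).}
#'   \item{Richards}{no lag; free \eqn{N_0, r, K, v} (k = 4).}
#'   \item{LogisticLag2}{\eqn{v = 1}; free \eqn{N_0, r, K, q_0, m} (k = 5).}
#'   \item{BaranyiRoberts}{all six parameters free (k = 6).}
#' }
#'
#' The no-lag limit is represented structurally (the adjustment factor is
#' identically 1), never by numeric infinities.
#'
#' @param name Model name, one of `"Logistic"`, `"Richards"`,
#'   `"LogisticLag2"`, `"BaranyiRoberts"`.
#' @return A `model_spec` object: list with `name`, `free` (free parameter
#'   names), `k` (their count), `v_fixed` (1 or `NA`), `lag` (logical).
#' @examples
#' model_spec("Logistic")
#' growth_model_family()
#' @export
model_spec <- function(name = c("Logistic", "Richards", "LogisticLag2",
                                "BaranyiRoberts")) {
  name <- match.arg(name)
  free <- switch(name,
    Logistic       = c("n0", "r", "k"),
    Richards       = c("n0", "r", "k", "v"),
    LogisticLag2   = c("n0", "r", "k", "q0", "m"),
    BaranyiRoberts = c("n0", "r", "k", "v", "q0", "m")
  )
  structure(
    list(
      name = name,
      free = free,
      k = length(free),
      v_fixed = if ("v" %in% free) NA_real_ else 1,
      lag = "q0" %in% free
    ),
    class = "model_spec"
  )
}

#' @rdname model_spec
#' @export
growth_model_family <- function() {
  lapply(c("Logistic", "Richards", "LogisticLag2", "BaranyiRoberts"),
         model_spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, " (k = ", x$k, "; free: ",
      paste(x$free, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Growth model parameters
#'
#' Bundles the parameters of the Baranyi-Roberts family. `n0` is the initial
#' density (OD units), `r` the intrinsic rate constant (per hour), `k` the
#' carrying capacity (OD), `v` the Richards deceleration/shape parameter,
#' and `q0` (initial physiological state, dimensionless) and `m`
#' (adjustment rate, per hour) control the lag. For no-lag models `q0` and
#' `m` are both `NA`; they must be supplied or omitted together.
#'
#' @param n0,r,k,v,q0,m Numeric scalars; see Description.
#' @return A `growth_params` object (named list).
#' @examples
#' growth_params(n0 = 0.15, r = 0.4, k = 1.26, v = 1, q0 = 0.2, m = 0.5)
#' @export
growth_params <- function(n0, r, k, v = 1, q0 = NA_real_, m = NA_real_) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1) {
      abort(paste0("`", nm, "` must be a numeric scalar."),
            class = "growthmedia_domain_error")
    }
    as.double(x)
  }
  p <- list(n0 = num1(n0, "n0"), r = num1(r, "r"), k = num1(k, "k"),
            v = num1(v, "v"), q0 = num1(q0, "q0"), m = num1(m, "m"))
  bad <- function(msg) abort(msg, class = "growthmedia_domain_error")
  if (!all(is.finite(c(p$n0, p$r, p$k, p$v)))) {
    bad("n0, r, k and v must be finite.")
  }
  if (p$n0 <= 0 || p$k <= p$n0) bad("Require 0 < n0 < k.")
  if (p$r <= 0) bad("Require r > 0.")
  if (p$v <= 0) bad("Require v > 0.")
  if (is.na(p$q0) != is.na(p$m)) {
    bad("q0 and m must be both present (lagged) or both NA (no lag).")
  }
  if (!is.na(p$q0) && (p$q0 <= 0 || p$m <= 0 || !is.finite(p$q0) ||
                       !is.finite(p$m))) {
    bad("When present, q0 and m must be finite and > 0.")
  }
  structure(p, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  print(vapply(unclass(x), identity, numeric(1)))
  invisible(x)
}

has_lag <- function(params) !is.na(params$q0)

# check params against a spec's fixed constraints (v = 1 and/or no lag)
check_params_spec <- function(params, spec) {
  if (!is.na(spec$v_fixed) && abs(params$v - spec$v_fixed) > 1e-12) {
    abort(paste0(spec$name, " fixes v = ", spec$v_fixed, "."),
          class = "growthmedia_domain_error")
  }
  if (!spec$lag && has_lag(params)) {
    abort(paste0(spec$name, " is a no-lag model; q0 and m must be NA."),
          class = "growthmedia_domain_error")
  }
  if (spec$lag && !has_lag(params)) {
    abort(paste0(spec$name, " needs q0 and m."),
          class = "growthmedia_domain_error")
  }
  invisible(params)
}

# log(1 + e^x) without overflow
softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Baranyi-Roberts adjustment function
#'
#' Computes the physiological adjustment factor
#' \eqn{\alpha(t) = q_0/(q_0 + e^{-m t})} and its integral
#' \eqn{A(t) = t + (1/m)\log((e^{-m t} + q_0)/(1 + q_0))}, the "adjusted
#' time" that replaces \eqn{t} in the lagged closed forms. \eqn{A(0) = 0},
#' \eqn{A} is nondecreasing, \eqn{A(t) \le t}, and
#' \eqn{t - A(t) \to (1/m)\log(1 + 1/q_0)} — the asymptotic lag deficit.
#'
#' @param q0 Initial physiological state (> 0).
#' @param m Adjustment rate, per hour (> 0).
#' @param times Times in hours (>= 0).
#' @return A tibble with columns `time`, `alpha` (in (0, 1]) and `a_hours`.
#' @examples
#' adjustment(q0 = 1, m = 1, times = c(0, 1, 20))
#' @export
adjustment <- function(q0, m, times) {
  if (!is.numeric(q0) || length(q0) != 1 || !is.finite(q0) || q0 <= 0 ||
      !is.numeric(m) || length(m) != 1 || !is.finite(m) || m <= 0) {
    abort("q0 and m must be finite scalars > 0.",
          class = "growthmedia_domain_error")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("times must be finite and >= 0.",
          class = "growthmedia_domain_error")
  }
  e <- exp(-m * times)
  tibble::tibble(
    time = times,
    alpha = q0 / (q0 + e),
    a_hours = times + log((e + q0) / (1 + q0)) / m
  )
}

# internal: A(t) for possibly no-lag params
adjusted_time <- function(params, times) {
  if (!has_lag(params)) return(times)
  times + log((exp(-params$m * times) + params$q0) / (1 + params$q0)) /
    params$m
}

alpha_at <- function(params, times) {
  if (!has_lag(params)) return(rep(1, length(times)))
  params$q0 / (params$q0 + exp(-params$m * times))
}

#' Evaluate a growth model
#'
#' Evaluates the closed-form density \eqn{N(t)} of a member of the
#' Baranyi-Roberts family. Exponentials are evaluated in log space so valid
#' parameter sets never produce `NaN` or overflow; output is clipped to
#' `(0, k]` only to absorb last-bit rounding.
#'
#' @param params A [growth_params()] object.
#' @param times Times in hours (finite, >= 0).
#' @param spec Optional [model_spec()]; if supplied, `params` are checked
#'   against its fixed constraints.
#' @return Numeric vector of densities, same length as `times`.
#' @examples
#' p <- growth_params(n0 = 0.1, r = 1, k = 1)
#' evaluate_growth(p, times = c(0, log(9)))  # 0.1 then the midpoint 0.5
#' @export
evaluate_growth <- function(params, times, spec = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.null(spec)) check_params_spec(params, spec)
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("times must be finite and >= 0.",
          class = "growthmedia_domain_error")
  }
  with(params, {
    # log((k/n0)^v - 1), stable for any v*log(k/n0) > 0
    vl <- v * log(k / n0)
    log_e <- vl + log1p(-exp(-vl))
    x <- log_e - r * v * adjusted_time(params, times)
    n <- k * exp(-softplus(x) / v)
    pmin(pmax(n, .Machine$double.xmin), k)
  })
}

#' Growth rate of a model
#'
#' Evaluates \eqn{dN/dt = r\,\alpha(t)\,N\,(1 - (N/K)^v)} along the
#' closed-form trajectory (\eqn{\alpha \equiv 1} for no-lag models).
#' Nonnegative whenever \eqn{0 < N_0 < K}.
#'
#' @inheritParams evaluate_growth
#' @return Numeric vector of densities per hour.
#' @examples
#' p <- growth_params(n0 = 0.5, r = 2, k = 1)
#' growth_rate(p, times = 0)  # 2 * 0.5 * (1 - 0.5) = 0.5
#' @export
growth_rate <- function(params, times, spec = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.null(spec)) check_params_spec(params, spec)
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("times must be finite and >= 0.",
          class = "growthmedia_domain_error")
  }
  n <- evaluate_growth(params, times)
  with(params, {
    vl <- v * log(k / n0)
    log_e <- vl + log1p(-exp(-vl))
    x <- log_e - r * v * adjusted_time(params, times)
    # (N/K)^v = 1/(1 + e^x), so 1 - (N/K)^v = plogis(x)
    r * alpha_at(params, times) * n * plogis(x)
  })
}

#' Numerically integrate a growth model
#'
#' Integrates the differential form
#' \eqn{dN/dt = r\,\alpha(t)\,N\,(1 - (N/K)^v)} with an adaptive
#' Dormand-Prince Runge-Kutta scheme. This is the numerical oracle for
#' [evaluate_growth()]: the two agree to within solver tolerance.
#'
#' @inheritParams evaluate_growth
#' @param times Strictly increasing times starting at 0.
#' @param tol Relative tolerance (absolute tolerance is `tol * 1e-2`).
#' @return Numeric vector of densities at `times`.
#' @examples
#' p <- growth_params(n0 = 0.1, r = 0.8, k = 1.2)
#' max(abs(integrate_ode(p, seq(0, 10, 0.5)) -
#'         evaluate_growth(p, seq(0, 10, 0.5))))
#' @export
integrate_ode <- function(params, times, tol = 1e-8, spec = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.null(spec)) check_params_spec(params, spec)
  if (length(times) < 1 || times[1] != 0 ||
      (length(times) > 1 && any(diff(times) <= 0))) {
    abort("times must be strictly increasing and start at 0.",
          class = "growthmedia_domain_error")
  }
  f <- function(t, y) {
    n <- max(y[1], 0)
    with(params,
         r * alpha_at(params, t) * n * (1 - (n / k)^v))
  }
  sol <- rk45(f, y0 = params$n0, times = times,
              rtol = tol, atol = tol * 1e-2,
              context = list(params = unclass(params)))
  as.numeric(sol[, 1])
}
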