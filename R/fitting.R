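# Bounded least-squares fitting of the model family.
#
# Parameters are optimised on a transformed scale: n0 = k * plogis(theta1)
# (so n0 < k holds by construction) and log scale for r, k, v, q0, m, with
# box bounds from fit_bounds(). Replicate wells are pooled into one residual
# vector; no averaging, so n in the BIC penalty is the true point count.

fit_bounds <- function() {
  list(
    s  = c(1e-6, 0.9999),   # n0 / k
    r  = c(1e-3, 10),
    k  = c(1e-3, 10),
    v  = c(0.05, 20),
    q0 = c(1e-4, 1e4),
    m  = c(1e-3, 20)
  )
}

# theta vector layout per spec: named transformed free parameters
params_to_theta <- function(params, spec) {
  th <- c(
    s  = qlogis(min(max(params$n0 / params$k, 1.001e-6), 0.99985)),
    r  = log(params$r),
    k  = log(params$k),
    v  = log(params$v),
    q0 = if (has_lag(params)) log(params$q0) else NA_real_,
    m  = if (has_lag(params)) log(params$m) else NA_real_
  )
  free <- spec$free
  free[free == "n0"] <- "s"
  th[free]
}

theta_to_params <- function(theta, spec) {
  get_th <- function(nm, default) if (nm %in% names(theta)) theta[[nm]] else default
  k <- exp(get_th("k", log(1)))
  s <- plogis(get_th("s", qlogis(0.1)))
  growth_params(
    n0 = k * s,
    r = exp(get_th("r", log(0.5))),
    k = k,
    v = if (is.na(spec$v_fixed)) exp(get_th("v", 0)) else spec$v_fixed,
    q0 = if (spec$lag) exp(get_th("q0", 0)) else NA_real_,
    m = if (spec$lag) exp(get_th("m", log(0.5))) else NA_real_
  )
}

theta_bounds <- function(spec) {
  b <- fit_bounds()
  free <- spec$free
  free[free == "n0"] <- "s"
  lower <- vapply(free, function(nm) {
    if (nm == "s") qlogis(b$s[1]) else log(b[[nm]][1])
  }, numeric(1))
  upper <- vapply(free, function(nm) {
    if (nm == "s") qlogis(b$s[2]) else log(b[[nm]][2])
  }, numeric(1))
  list(lower = setNames(lower, free), upper = setNames(upper, free))
}

#' Heuristic starting parameters for a growth-curve fit
#'
#' Derives plausible initial parameter values from the data: `n0` from the
#' mean OD at the earliest time, `k` from the 95th percentile of the last
#' quarter of the series, `r` from the steepest slope of log(OD) between
#' consecutive per-timepoint means (clipped to a small positive minimum for
#' non-growing series), `v = 1`, `q0 = 1`, `m = r`.
#'
#' @param curve A [growth_curve()] with at least 8 distinct timepoints and
#'   non-zero OD range.
#' @param spec A [model_spec()]; lag parameters are only populated for
#'   lagged specs.
#' @return A [growth_params()] object.
#' @export
guess_initial_parameters <- function(curve, spec) {
  stopifnot(inherits(curve, "growth_curve"), inherits(spec, "model_spec"))
  times <- curve_times(curve)
  if (length(times) < 8) {
    abort("Need at least 8 distinct timepoints.",
          class = "growthmedia_degenerate_input")
  }
  if (diff(range(curve$od)) <= 1e-6) {
    abort("Flat series: OD range is (numerically) zero.",
          class = "growthmedia_degenerate_input")
  }
  mean_od <- curve |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(od = mean(.data$od), .groups = "drop") |>
    dplyr::arrange(.data$time)
  b <- fit_bounds()
  od_floor <- 1e-3
  last_quarter <- mean_od$od[mean_od$time >=
                               quantile(mean_od$time, 0.75, names = FALSE)]
  k_guess <- max(quantile(last_quarter, 0.95, names = FALSE), 2 * od_floor)
  k_guess <- min(max(k_guess, b$k[1]), b$k[2])
  n0_guess <- max(mean(curve$od[curve$time == times[1]]), od_floor)
  n0_guess <- min(n0_guess, 0.9 * k_guess)
  log_od <- log(pmax(mean_od$od, od_floor))
  slopes <- diff(log_od) / diff(mean_od$time)
  r_guess <- min(max(max(slopes), b$r[1]), b$r[2])
  growth_params(
    n0 = n0_guess, r = r_guess, k = k_guess,
    v = if (is.na(spec$v_fixed)) 1 else spec$v_fixed,
    q0 = if (spec$lag) 1 else NA_real_,
    m = if (spec$lag) r_guess else NA_real_
  )
}

#' Bayesian information criterion for a least-squares fit
#'
#' \eqn{\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n} (natural
#' logarithm), the Gaussian-residual form appropriate for least-squares
#' model comparison. Lower is better. A perfect fit (`rss = 0`) is
#' degenerate: the criterion is `-Inf` and family ranking falls back to the
#' parameter count.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of fitted points (> k).
#' @param k Number of free parameters (>= 1).
#' @return The criterion value (scalar; `-Inf` when `rss = 0`).
#' @examples
#' compute_bic(rss = 144, n = 144, k = 6)  # 6 * log(144)
#' @export
compute_bic <- function(rss, n, k) {
  if (!is.numeric(rss) || rss < 0 || !is.finite(rss)) {
    abort("rss must be finite and >= 0.", class = "growthmedia_domain_error")
  }
  if (k < 1 || n <= k) {
    abort("Require n > k >= 1.", class = "growthmedia_domain_error")
  }
  if (rss == 0) return(-Inf)
  n * log(rss / n) + k * log(n)
}

rss_objective <- function(curve) {
  t_obs <- curve$time
  od_obs <- curve$od
  function(theta, spec) {
    params <- tryCatch(theta_to_params(setNames(theta, names(theta)), spec),
                       error = function(e) NULL)
    if (is.null(params)) return(1e10)
    pred <- evaluate_growth(params, t_obs)
    if (any(!is.finite(pred))) return(1e10)
    sum((pred - od_obs)^2)
  }
}

#' Fit one growth model by bounded least squares
#'
#' Minimises the pooled residual sum of squares over all replicate wells
#' with box-bounded parameters (L-BFGS-B on a log/logit-transformed scale),
#' running a fixed number of seeded, jittered multi-starts and keeping the
#' lowest-RSS converged result.
#'
#' @param curve A [growth_curve()].
#' @param spec A [model_spec()].
#' @param init Optional [growth_params()] starting point; defaults to
#'   [guess_initial_parameters()]. A list of several starting points may
#'   also be given.
#' @param seed Integer seed for the start jitter.
#' @param n_starts Number of multi-starts (the first is unjittered).
#' @return A `growth_fit` object: list with `spec`, `params`, `rss`, `n`,
#'   `k`, `bic`, `converged`, and the fitted `curve`.
#' @examples
#' p <- growth_params(n0 = 0.1, r = 0.8, k = 1.2)
#' gc <- growth_curve(data.frame(time = seq(0, 24, 0.5), well = "A1",
#'                               od = evaluate_growth(p, seq(0, 24, 0.5))))
#' fit <- fit_single_model(gc, model_spec("Logistic"))
#' glance(fit)
#' @export
fit_single_model <- function(curve, spec, init = NULL, seed = 1L,
                             n_starts = 5L) {
  stopifnot(inherits(curve, "growth_curve"), inherits(spec, "model_spec"))
  inits <- if (is.null(init)) {
    list(guess_initial_parameters(curve, spec))
  } else if (inherits(init, "growth_params")) {
    list(init)
  } else {
    init
  }
  obj <- rss_objective(curve)
  bounds <- theta_bounds(spec)
  starts <- list()
  for (ip in inits) {
    th0 <- params_to_theta(ip, spec)
    th0 <- pmin(pmax(th0, bounds$lower), bounds$upper)
    starts <- c(starts, list(th0))
  }
  # jittered starts: +/-20% log-uniform on the natural parameters
  starts <- c(starts, with_preserved_seed(seed, {
    lapply(seq_len(max(n_starts - length(starts), 0)), function(i) {
      base <- starts[[(i - 1) %% length(starts) + 1]]
      jit <- base + runif(length(base), log(0.8), log(1.2))
      pmin(pmax(jit, bounds$lower), bounds$upper)
    })
  }))
  results <- list()
  diagnostics <- character()
  for (th0 in starts) {
    res <- tryCatch(
      optim(th0, obj, spec = spec, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      diagnostics <- c(diagnostics, "optim error")
      next
    }
    if (res$convergence != 0) {
      diagnostics <- c(diagnostics,
                       paste0("convergence=", res$convergence,
                              if (nzchar(res$message %||% ""))
                                paste0(" (", res$message, ")") else ""))
    }
    results <- c(results, list(res))
  }
  codes <- vapply(results, function(r) r$convergence, numeric(1))
  values <- vapply(results, function(r) r$value, numeric(1))
  if (!any(codes == 0)) {
    abort(paste0("No start converged for ", spec$name, ". [",
                 paste(unique(diagnostics), collapse = "; "), "]"),
          class = "growthmedia_convergence_error")
  }
  # lowest-RSS converged start wins; a start that stopped with a line-search
  # warning is accepted only if it is at least as good as a converged one
  # (the flat-optimum pathology, not a failure to fit)
  best_conv <- min(values[codes == 0])
  usable <- codes == 0 | values <= best_conv
  best <- results[usable][[which.min(values[usable])]]
  params <- theta_to_params(setNames(best$par, names(bounds$lower)), spec)
  n <- nrow(curve)
  rss <- best$value
  structure(
    list(
      spec = spec,
      params = params,
      rss = rss,
      n = n,
      k = spec$k,
      bic = compute_bic(rss, n, spec$k),
      converged = TRUE,  # by construction: validated against a code-0 start
      curve = curve
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$spec$name, ": rss = ", signif(x$rss, 4),
      ", n = ", x$n, ", k = ", x$k, ", BIC = ", signif(x$bic, 6),
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

# promote a fitted simpler model's parameters to a more complex spec
promote_params <- function(params, to_spec, r_fallback = 0.5) {
  growth_params(
    n0 = params$n0, r = params$r, k = params$k,
    v = if (is.na(to_spec$v_fixed)) params$v else to_spec$v_fixed,
    q0 = if (to_spec$lag) { if (has_lag(params)) params$q0 else 1 }
         else NA_real_,
    m = if (to_spec$lag) { if (has_lag(params)) params$m else params$r }
        else NA_real_
  )
}

# ordering that favours fewer parameters within a BIC tie margin
rank_fits <- function(fits, tie_margin = 2) {
  better <- function(a, b) {
    if (is.infinite(a$bic) && is.infinite(b$bic)) return(a$k < b$k)
    if (is.infinite(a$bic)) return(TRUE)
    if (is.infinite(b$bic)) return(FALSE)
    if (abs(a$bic - b$bic) <= tie_margin) {
      if (a$k != b$k) return(a$k < b$k)
      return(a$bic < b$bic)
    }
    a$bic < b$bic
  }
  ord <- seq_along(fits)
  # insertion sort under the non-transitive-safe comparator (n is tiny)
  for (i in seq_along(ord)[-1]) {
    j <- i
    while (j > 1 && better(fits[[ord[j]]], fits[[ord[j - 1]]])) {
      tmp <- ord[j]; ord[j] <- ord[j - 1]; ord[j - 1] <- tmp
      j <- j - 1
    }
  }
  ord
}

#' Fit the nested growth-model family and rank by BIC
#'
#' Fits each model of the family (ordered simple to complex), warm-starting
#' every more complex model from the best already-fitted nested model, and
#' ranks results by ascending BIC. Fits whose BIC differ by at most
#' `tie_margin` are ordered by parameter count (fewer first); perfect fits
#' (`rss = 0`) rank by parameter count alone.
#'
#' @inheritParams fit_single_model
#' @param family List of [model_spec()]s, simple to complex. Defaults to
#'   [growth_model_family()].
#' @param tie_margin BIC difference treated as a tie (default 2).
#' @return A `growth_fit_family` tibble with one row per model (columns
#'   `model`, `k`, `n`, `rss`, `bic`, `rank`, `converged`, list-column
#'   `fit`), ordered by rank.
#' @export
fit_model_family <- function(curve, family = growth_model_family(),
                             seed = 1L, n_starts = 5L, tie_margin = 2) {
  stopifnot(length(family) >= 1)
  fits <- list()
  failures <- character()
  for (i in seq_along(family)) {
    spec <- family[[i]]
    inits <- list(tryCatch(guess_initial_parameters(curve, spec),
                           error = function(e) NULL))
    # warm starts from the best nested simpler fit(s)
    if (length(fits)) {
      prev <- fits[[which.min(vapply(fits, function(f) f$rss, numeric(1)))]]
      inits <- c(inits, list(promote_params(prev$params, spec)))
    }
    inits <- Filter(Negate(is.null), inits)
    fit <- tryCatch(
      fit_single_model(curve, spec, init = inits, seed = seed + i,
                       n_starts = n_starts),
      error = function(e) {
        failures <<- c(failures, paste0(spec$name, ": ", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(fit)) fits <- c(fits, list(fit))
  }
  if (!length(fits)) {
    abort(paste0("All model fits failed. ",
                 paste(failures, collapse = " | ")),
          class = "growthmedia_convergence_error")
  }
  ord <- rank_fits(fits, tie_margin = tie_margin)
  out <- tibble::tibble(
    model = vapply(fits, function(f) f$spec$name, character(1))[ord],
    k = vapply(fits, function(f) f$k, numeric(1))[ord],
    n = vapply(fits, function(f) f$n, numeric(1))[ord],
    rss = vapply(fits, function(f) f$rss, numeric(1))[ord],
    bic = vapply(fits, function(f) f$bic, numeric(1))[ord],
    rank = seq_along(ord),
    converged = vapply(fits, function(f) f$converged, logical(1))[ord],
    fit = fits[ord]
  )
  structure(out,
            class = c("growth_fit_family", class(tibble::tibble())),
            curve = curve)
}

#' Best fit of a ranked family
#'
#' @param family_fit A `growth_fit_family` from [fit_model_family()].
#' @return The rank-1 `growth_fit`.
#' @export
best_fit <- function(family_fit) {
  stopifnot(inherits(family_fit, "growth_fit_family"))
  family_fit$fit[[which(family_fit$rank == 1)]]
}
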