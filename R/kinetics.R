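# Derived kinetic summaries from a fitted (or given) model.
#
# All statistics come from the fitted curve, never from smoothed raw data:
# a dense grid scan (default step 0.01 h) locates the maxima, then each is
# refined by a local 1-D optimisation so results are reproducible and
# oracle-checkable.

kinetics_from_params <- function(params, window, grid_step = 0.01,
                                 model_name = NA_character_) {
  stopifnot(window[2] > window[1], grid_step > 0)
  grid <- seq(window[1], window[2], by = grid_step)
  n_grid <- evaluate_growth(params, grid)
  dn_grid <- growth_rate(params, grid)

  refine_max <- function(f, t0) {
    lo <- max(window[1], t0 - grid_step)
    hi <- min(window[2], t0 + grid_step)
    if (hi <= lo) return(list(t = t0, value = f(t0)))
    op <- optimize(f, c(lo, hi), maximum = TRUE,
                   tol = .Machine$double.eps^0.5)
    if (op$objective >= f(t0)) list(t = op$maximum, value = op$objective)
    else list(t = t0, value = f(t0))
  }

  # maximum specific (per-capita) growth rate: max over t of (1/N) dN/dt
  percap <- function(t) growth_rate(params, t) / evaluate_growth(params, t)
  mu_peak <- refine_max(percap, grid[which.max(dn_grid / n_grid)])
  mu_max <- mu_peak$value

  # lag: tangent at the point of maximum derivative, intersected with N0
  dmax <- refine_max(function(t) growth_rate(params, t),
                     grid[which.max(dn_grid)])
  t_star <- dmax$t
  slope <- dmax$value
  lag <- if (slope > 0) {
    max(0, t_star - (evaluate_growth(params, t_star) - params$n0) / slope)
  } else {
    0
  }

  auc <- sum(diff(grid) * (head(n_grid, -1) + tail(n_grid, -1)) / 2)

  tibble::tibble(
    initial_density = params$n0,
    max_density = params$k,
    mu_max = mu_max,
    min_doubling_time = log(2) / mu_max,
    lag_hours = lag,
    auc = auc,
    best_model_name = model_name
  )
}

#' Derive kinetic summaries from a fitted model
#'
#' Computes, from the fitted curve on a dense grid over the observation
#' window: the maximum specific growth rate
#' \eqn{\mu_{max} = \max_t (1/N)(dN/dt)}; the minimum doubling time
#' \eqn{\ln(2)/\mu_{max}}; the lag phase \eqn{\lambda}, defined by the
#' tangent to \eqn{N(t)} at the point of maximum derivative intersecting
#' the initial density \eqn{N_0} (clipped at 0); the maximum density (the
#' model asymptote \eqn{K}); and the trapezoidal area under the fitted
#' curve (AUC, OD x hours).
#'
#' @param fit A converged `growth_fit`, a `growth_fit_family` (its rank-1
#'   fit is used), or a [growth_params()] object.
#' @param window Length-2 numeric time span in hours; defaults to the
#'   fitted data's observation window (required for bare parameters).
#' @param grid_step Grid resolution in hours (default 0.01).
#' @return A one-row `kinetic_summary` tibble: `initial_density`,
#'   `max_density`, `mu_max`, `min_doubling_time`, `lag_hours`, `auc`,
#'   `best_model_name`.
#' @examples
#' p <- growth_params(n0 = 0.01, r = 1, k = 1)
#' derive_kinetics(p, window = c(0, 24))  # mu_max ~ r (1 - n0/k) = 0.99
#' @export
derive_kinetics <- function(fit, window = NULL, grid_step = 0.01) {
  if (inherits(fit, "growth_fit_family")) fit <- best_fit(fit)
  if (inherits(fit, "growth_params")) {
    if (is.null(window)) {
      abort("`window` is required when summarising bare parameters.",
            class = "growthmedia_domain_error")
    }
    return(kinetics_from_params(fit, window, grid_step))
  }
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged)) {
    abort("Refusing to summarise a non-converged fit.",
          class = "growthmedia_convergence_error")
  }
  window <- window %||% range(fit$curve$time)
  kinetics_from_params(fit$params, window, grid_step,
                       model_name = fit$spec$name)
}

#' Recover Baranyi-Roberts parameters from a kinetic summary
#'
#' Numerically inverts the kinetics map: finds lagged model parameters
#' (with `v` fixed, default 1) whose derived maximum specific growth rate
#' and lag phase equal the given summary values, with `n0` and `k` taken
#' as printed. The system is closed with the common Baranyi convention
#' `m = r` (one adjustment timescale), leaving two unknowns `(r, q0)` for
#' the two targets.
#'
#' @param n0 Initial density (OD).
#' @param k Maximum density (OD).
#' @param mu_max Maximum specific growth rate (per hour).
#' @param lag_hours Lag phase duration (hours).
#' @param v Shape parameter to fix (default 1).
#' @param window Time window over which the summaries are defined (hours).
#' @return A [growth_params()] object whose [derive_kinetics()] summaries
#'   reproduce `mu_max` and `lag_hours`.
#' @examples
#' p <- params_from_summary(n0 = 0.13, k = 1.37, mu_max = 0.59,
#'                          lag_hours = 2.27)
#' derive_kinetics(p, window = c(0, 36))[, c("mu_max", "lag_hours")]
#' @export
params_from_summary <- function(n0, k, mu_max, lag_hours, v = 1,
                                window = c(0, 36)) {
  if (mu_max <= 0 || lag_hours < 0 || n0 <= 0 || k <= n0) {
    abort("Need mu_max > 0, lag_hours >= 0, 0 < n0 < k.",
          class = "growthmedia_domain_error")
  }
  make <- function(th) {
    r <- exp(th[1])
    growth_params(n0 = n0, r = r, k = k, v = v,
                  q0 = exp(th[2]), m = r)
  }
  objective <- function(th) {
    p <- tryCatch(make(th), error = function(e) NULL)
    if (is.null(p)) return(1e6)
    ks <- kinetics_from_params(p, window, grid_step = 0.02)
    log(ks$mu_max / mu_max)^2 +
      ((ks$lag_hours - lag_hours) / max(lag_hours, 0.5))^2
  }
  # Baranyi small-q0 relation lag ~ (1/m) log(1 + 1/q0) seeds the search
  r0 <- mu_max / 0.8
  q0_0 <- 1 / expm1(max(r0 * lag_hours, 1e-3))
  res <- optim(c(log(r0), log(q0_0)), objective, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-12))
  if (res$value > 1e-4) {
    abort(paste0("Summary inversion did not reach the targets ",
                 "(residual ", signif(res$value, 3), ")."),
          class = "growthmedia_convergence_error")
  }
  make(res$par)
}
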