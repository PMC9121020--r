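#' Two-strain Lotka-Volterra competition setup
#'
#' Pairs two strains' monoculture growth parameters with competition
#' coefficients and inoculum densities for mixed-culture simulation. The
#' coefficient `c1` scales the pressure of strain 1 on strain 2, `c2` the
#' pressure of strain 2 on strain 1; with no mixed-culture data to fit
#' them, both default to 1 (inter-strain competition as strong as
#' intra-strain).
#'
#' @param strain1,strain2 [growth_params()] for each strain (typically from
#'   monoculture best fits).
#' @param label1,label2 Strain labels.
#' @param c1,c2 Competition coefficients (>= 0).
#' @param inoculum1,inoculum2 Initial densities (OD, >= 0); default to each
#'   strain's fitted `n0`.
#' @return A `competition_setup` object.
#' @export
competition_setup <- function(strain1, strain2,
                              label1 = "strain1", label2 = "strain2",
                              c1 = 1, c2 = 1,
                              inoculum1 = strain1$n0,
                              inoculum2 = strain2$n0) {
  stopifnot(inherits(strain1, "growth_params"),
            inherits(strain2, "growth_params"))
  if (!is.finite(c1) || !is.finite(c2) || c1 < 0 || c2 < 0) {
    abort("Competition coefficients must be finite and >= 0.",
          class = "growthmedia_domain_error")
  }
  if (inoculum1 < 0 || inoculum2 < 0) {
    abort("Inocula must be >= 0.", class = "growthmedia_domain_error")
  }
  structure(
    list(strain1 = strain1, strain2 = strain2,
         label1 = label1, label2 = label2,
         c1 = c1, c2 = c2,
         inoculum1 = inoculum1, inoculum2 = inoculum2),
    class = "competition_setup"
  )
}

#' Simulate two-strain Lotka-Volterra competition
#'
#' Integrates the coupled system
#' \deqn{dN_1/dt = r_1 \alpha_1(t) N_1 (1 - N_1^{v_1}/K_1^{v_1}
#'       - c_2 N_2^{v_2}/K_1^{v_1})}
#' \deqn{dN_2/dt = r_2 \alpha_2(t) N_2 (1 - c_1 N_1^{v_1}/K_2^{v_2}
#'       - N_2^{v_2}/K_2^{v_2})}
#' where \eqn{\alpha_i} is each strain's Baranyi-Roberts adjustment factor
#' (1 for no-lag parameters). By default each equation's own carrying
#' capacity normalises both density terms (`cross_k = "resident"`);
#' `cross_k = "competitor"` instead normalises each cross term by the
#' competitor's capacity.
#'
#' @param setup A [competition_setup()].
#' @param times Strictly increasing times from 0 (hours).
#' @param tol Relative integration tolerance.
#' @param cross_k Normalisation of the cross-competition term (see above).
#' @return A `competition_trajectory` tibble with columns `time`, `n1`,
#'   `n2`; attribute `final_fraction1` holds strain 1's final share.
#' @export
simulate_competition <- function(setup, times, tol = 1e-8,
                                 cross_k = c("resident", "competitor")) {
  stopifnot(inherits(setup, "competition_setup"))
  cross_k <- match.arg(cross_k)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    abort("times must be strictly increasing and start at 0.",
          class = "growthmedia_domain_error")
  }
  p1 <- setup$strain1
  p2 <- setup$strain2
  k1v <- p1$k^p1$v
  k2v <- p2$k^p2$v
  cross1_den <- if (cross_k == "resident") k1v else k2v
  cross2_den <- if (cross_k == "resident") k2v else k1v
  f <- function(t, y) {
    n1 <- max(y[1], 0)
    n2 <- max(y[2], 0)
    a1 <- alpha_at(p1, t)
    a2 <- alpha_at(p2, t)
    c(
      p1$r * a1 * n1 * (1 - n1^p1$v / k1v - setup$c2 * n2^p2$v / cross1_den),
      p2$r * a2 * n2 * (1 - setup$c1 * n1^p1$v / cross2_den - n2^p2$v / k2v)
    )
  }
  sol <- rk45(f, y0 = c(setup$inoculum1, setup$inoculum2), times = times,
              rtol = tol, atol = tol * 1e-2,
              context = list(strain1 = unclass(p1), strain2 = unclass(p2),
                             c1 = setup$c1, c2 = setup$c2))
  n1 <- pmax(sol[, 1], 0)
  n2 <- pmax(sol[, 2], 0)
  total <- n1 + n2
  last_pos <- which(total > 0)
  frac1 <- if (length(last_pos)) {
    i <- max(last_pos)
    n1[i] / total[i]
  } else {
    NA_real_
  }
  structure(
    tibble::tibble(time = times, n1 = n1, n2 = n2),
    class = c("competition_trajectory", class(tibble::tibble())),
    label1 = setup$label1, label2 = setup$label2,
    final_fraction1 = frac1
  )
}

#' Summarise a competition trajectory
#'
#' Reports final densities and fractions and the earliest crossover time:
#' the first time at which the initially leading strain is overtaken
#' (absent if the lead never changes).
#'
#' @param traj A `competition_trajectory` from [simulate_competition()].
#' @return A one-row tibble: `final_n1`, `final_n2`, `final_fraction1`,
#'   `final_fraction2`, `crossover_time` (`NA` if none).
#' @export
summarize_competition <- function(traj) {
  stopifnot(inherits(traj, "competition_trajectory"))
  if (!nrow(traj)) {
    abort("Empty trajectory.", class = "growthmedia_domain_error")
  }
  last <- traj[nrow(traj), ]
  total <- last$n1 + last$n2
  d <- traj$n1 - traj$n2
  lead0 <- sign(d[which(d != 0)[1]])
  crossover <- NA_real_
  if (!is.na(lead0)) {
    flipped <- which(sign(d) == -lead0)
    if (length(flipped)) crossover <- traj$time[flipped[1]]
  }
  tibble::tibble(
    final_n1 = last$n1,
    final_n2 = last$n2,
    final_fraction1 = if (total > 0) last$n1 / total else NA_real_,
    final_fraction2 = if (total > 0) last$n2 / total else NA_real_,
    crossover_time = crossover
  )
}
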