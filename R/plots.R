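# ggplot2 displays for the main result types.

#' Plot a fitted growth model over its data
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot: pooled replicate readings (points) with the fitted
#'   curve overlaid.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  curve <- object$curve
  grid <- tibble::tibble(
    time = seq(min(curve$time), max(curve$time), length.out = 400))
  grid$od <- evaluate_growth(object$params, grid$time)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$od)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#d1495b", linewidth = 0.9) +
    ggplot2::labs(x = "Time (h)", y = "OD600",
                  title = paste0(object$spec$name, " fit"),
                  subtitle = sprintf("RSS %.4g | BIC %.5g | k = %d",
                                     object$rss, object$bic, object$k)) +
    ggplot2::theme_minimal()
}

#' Plot every model of a ranked family fit
#'
#' @param object A `growth_fit_family`.
#' @param ... Unused.
#' @return A ggplot faceted by model, best (rank 1) first.
#' @method autoplot growth_fit_family
#' @export
autoplot.growth_fit_family <- function(object, ...) {
  curve <- attr(object, "curve")
  grids <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    f <- object$fit[[i]]
    g <- tibble::tibble(
      time = seq(min(curve$time), max(curve$time), length.out = 300))
    g$od <- evaluate_growth(f$params, g$time)
    g$model <- sprintf("%d. %s (BIC %.4g)", object$rank[i], f$spec$name,
                       object$bic[i])
    g
  }))
  grids$model <- factor(grids$model, levels = unique(grids$model))
  ggplot2::ggplot(grids, ggplot2::aes(x = .data$time, y = .data$od)) +
    ggplot2::geom_point(data = tibble::as_tibble(curve), alpha = 0.08,
                        size = 0.5) +
    ggplot2::geom_line(colour = "#d1495b", linewidth = 0.8) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Time (h)", y = "OD600") +
    ggplot2::theme_minimal()
}

#' Plot a two-strain competition trajectory
#'
#' @param object A `competition_trajectory`.
#' @param ... Unused.
#' @return A ggplot of both strains' densities over time.
#' @method autoplot competition_trajectory
#' @export
autoplot.competition_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("n1", "n2"),
                              names_to = "strain", values_to = "od")
  labels <- c(n1 = attr(object, "label1") %||% "strain 1",
              n2 = attr(object, "label2") %||% "strain 2")
  long$strain <- labels[long$strain]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$od,
                                     colour = .data$strain)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Time (h)", y = "OD600", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of single-omission essentiality calls
#'
#' @param calls A call tibble from [analyze_soe_table()].
#' @return A ggplot of relative growth per omitted component, coloured by
#'   call, with the 40/80% thresholds marked.
#' @export
plot_soe_calls <- function(calls) {
  calls <- tibble::as_tibble(calls)
  calls$omitted <- factor(calls$omitted, levels = rev(unique(calls$omitted)))
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$relative_growth_pct,
                               y = .data$omitted, fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(40, 80), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~strain) +
    ggplot2::labs(x = "Relative growth (% of complete medium)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
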