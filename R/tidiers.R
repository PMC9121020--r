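# broom-style tidiers for fitted objects.

#' Tidy a single growth-model fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter (`term`, `estimate`).
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  est <- unlist(unclass(x$params))[x$spec$free]
  tibble::tibble(term = x$spec$free, estimate = unname(est))
}

#' @rdname tidy.growth_fit
#' @return `glance()`: a one-row tibble with `model`, `rss`, `n`, `k`,
#'   `bic`, `converged`.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, rss = x$rss, n = x$n, k = x$k,
                 bic = x$bic, converged = x$converged)
}

#' Tidy a ranked model-family fit
#'
#' @param x A `growth_fit_family`.
#' @param ... Unused.
#' @return `tidy()`: one row per model and free parameter; `glance()`: the
#'   ranking table without the list column.
#' @method tidy growth_fit_family
#' @export
tidy.growth_fit_family <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fit, function(f) {
    dplyr::mutate(tidy(f), model = f$spec$name, .before = 1)
  }))
}

#' @rdname tidy.growth_fit_family
#' @method glance growth_fit_family
#' @export
glance.growth_fit_family <- function(x, ...) {
  tibble::as_tibble(x)[, c("model", "k", "n", "rss", "bic", "rank",
                           "converged")]
}
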