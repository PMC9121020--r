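# Single-omission experiment (SOE) analysis: relative growth, the
# essential / stimulatory / non-essential threshold rule, and batch
# classification of omission tables.

#' Relative growth of an omission culture
#'
#' 24-h growth in an omission medium as a percentage of growth in the
#' complete medium: `100 * od_omit_24h / od_control_24h`. Scale-invariant
#' in the OD calibration.
#'
#' @param od_omit_24h 24-h OD in the omission medium (>= 0).
#' @param od_control_24h 24-h OD in the complete medium (> 0).
#' @return Relative growth in percent (vectorised).
#' @examples
#' relative_growth(2.2, 4.4)  # 50
#' @export
relative_growth <- function(od_omit_24h, od_control_24h) {
  if (any(!is.finite(od_control_24h)) || any(od_control_24h <= 0)) {
    abort("Control OD must be finite and > 0.",
          class = "growthmedia_domain_error")
  }
  if (any(!is.finite(od_omit_24h)) || any(od_omit_24h < 0)) {
    abort("Omission OD must be finite and >= 0.",
          class = "growthmedia_domain_error")
  }
  100 * od_omit_24h / od_control_24h
}

#' Classify a medium component from its relative growth
#'
#' The threshold rule: a component is *essential* if its omission leaves
#' growth below 40% of the complete-medium control, *stimulatory* between
#' 40 and 80% (both ends inclusive), and *non-essential* above 80%.
#'
#' @param rel_pct Relative growth in percent (>= 0; vectorised).
#' @param thresholds Length-2 numeric: the essential/stimulatory and
#'   stimulatory/non-essential cutpoints (default `c(40, 80)`).
#' @return Character vector: `"essential"`, `"stimulatory"` or
#'   `"non_essential"`.
#' @examples
#' classify_essentiality(c(2, 60.24, 110.2, 40))
#' @export
classify_essentiality <- function(rel_pct, thresholds = c(40, 80)) {
  if (any(!is.finite(rel_pct)) || any(rel_pct < 0)) {
    abort("Relative growth must be finite and >= 0.",
          class = "growthmedia_domain_error")
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  dplyr::case_when(
    rel_pct < thresholds[1] ~ "essential",
    rel_pct <= thresholds[2] ~ "stimulatory",
    TRUE ~ "non_essential"
  )
}

#' Classify every row of a single-omission table
#'
#' Computes (or accepts precomputed) relative growth for each omission
#' observation and applies the threshold rule. Per-strain complete-medium
#' control ODs drive the computation; alternatively a
#' `relative_growth_pct` column in `observations` is used as-is (the form
#' in which published omission tables usually arrive).
#'
#' @param observations Data frame with columns `omitted`, `strain`,
#'   `od_0h`, `od_24h`, and optionally `relative_growth_pct`.
#' @param control_od_24h Named numeric: complete-medium 24-h OD per strain.
#'   May be omitted when `relative_growth_pct` is supplied.
#' @param thresholds Passed to [classify_essentiality()].
#' @return A tibble (`omitted`, `strain`, `relative_growth_pct`, `call`)
#'   in input row order.
#' @export
analyze_soe_table <- function(observations, control_od_24h = NULL,
                              thresholds = c(40, 80)) {
  obs <- tibble::as_tibble(observations)
  if (!nrow(obs)) {
    return(tibble::tibble(omitted = character(), strain = character(),
                          relative_growth_pct = numeric(),
                          call = character()))
  }
  need <- c("omitted", "strain")
  if (length(setdiff(need, names(obs)))) {
    abort("observations need `omitted` and `strain` columns.",
          class = "growthmedia_config_error")
  }
  if ("relative_growth_pct" %in% names(obs) &&
      all(is.finite(obs$relative_growth_pct))) {
    rel <- obs$relative_growth_pct
  } else {
    if (!all(c("od_0h", "od_24h") %in% names(obs))) {
      abort("Need od_0h/od_24h columns (or a relative_growth_pct column).",
            class = "growthmedia_config_error")
    }
    if (is.null(control_od_24h)) {
      abort("No control ODs and no precomputed relative growth supplied.",
            class = "growthmedia_config_error")
    }
    unknown <- setdiff(unique(obs$strain), names(control_od_24h))
    if (length(unknown)) {
      abort(paste0("No control OD for strain(s): ",
                   paste(unknown, collapse = ", ")),
            class = "growthmedia_config_error")
    }
    rel <- relative_growth(obs$od_24h,
                           unname(control_od_24h[obs$strain]))
  }
  tibble::tibble(
    omitted = obs$omitted,
    strain = obs$strain,
    relative_growth_pct = rel,
    call = classify_essentiality(rel, thresholds)
  )
}
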