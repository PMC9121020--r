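#' Plate-reader growth curve data
#'
#' A `growth_curve` is a tidy tibble of optical-density readings with
#' columns `time` (hours), `well` (well identifier) and `od` (OD600),
#' one row per (well, time) reading. All wells must share a common sampling
#' schedule (ragged data are rejected), every (well, time) pair must be
#' unique, and ODs must be finite.
#'
#' @param data A data frame with columns `time`, `well`, `od`.
#' @param strain Optional strain/condition label.
#' @param blank_corrected Logical; whether a blank correction has been
#'   applied.
#' @param well_meta Optional tibble of per-well metadata (must contain a
#'   `well` column), e.g. the strain each well carries.
#' @return A `growth_curve` tibble.
#' @examples
#' growth_curve(data.frame(time = rep(0:3, 2),
#'                         well = rep(c("A1", "A2"), each = 4),
#'                         od = c(0.1, 0.2, 0.4, 0.5, 0.1, 0.21, 0.39, 0.52)),
#'              strain = "demo")
#' @export
growth_curve <- function(data, strain = NULL, blank_corrected = FALSE,
                         well_meta = NULL) {
  data <- tibble::as_tibble(data)
  need <- c("time", "well", "od")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "growthmedia_parse_error")
  }
  if (!is.numeric(data$time) || !is.numeric(data$od)) {
    abort("`time` and `od` must be numeric.",
          class = "growthmedia_parse_error")
  }
  if (any(!is.finite(data$time)) || any(data$time < 0)) {
    abort("Times must be finite and >= 0.",
          class = "growthmedia_parse_error")
  }
  if (any(!is.finite(data$od))) {
    abort("ODs must be finite (no NA/NaN readings).",
          class = "growthmedia_parse_error")
  }
  data$well <- as.character(data$well)
  dup <- duplicated(data[c("well", "time")])
  if (any(dup)) {
    bad <- data[dup, ][1, ]
    abort(paste0("Duplicated reading for well ", bad$well, " at time ",
                 bad$time, " h."),
          class = "growthmedia_parse_error")
  }
  data <- dplyr::arrange(data, .data$well, .data$time)
  schedules <- split(data$time, data$well)
  ref <- schedules[[1]]
  same <- vapply(schedules, function(s) {
    length(s) == length(ref) && all(s == ref)
  }, logical(1))
  if (!all(same)) {
    abort(paste0("Wells do not share a common sampling schedule (first ",
                 "offender: well ", names(schedules)[which(!same)[1]], ")."),
          class = "growthmedia_parse_error")
  }
  structure(
    data,
    class = c("growth_curve", class(tibble::tibble())),
    strain_label = strain %||% NA_character_,
    blank_corrected = isTRUE(blank_corrected),
    well_meta = well_meta
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

curve_times <- function(curve) sort(unique(curve$time))

curve_wells <- function(curve) unique(curve$well)

#' @export
print.growth_curve <- function(x, ...) {
  cat("<growth_curve> ", length(curve_wells(x)), " well(s) x ",
      length(curve_times(x)), " timepoint(s)",
      if (!is.na(attr(x, "strain_label")))
        paste0("; strain: ", attr(x, "strain_label")) else "",
      if (isTRUE(attr(x, "blank_corrected"))) "; blank-corrected" else "",
      "\n", sep = "")
  NextMethod()
}

#' Blank-correct a growth curve
#'
#' Subtracts the per-timepoint mean of the designated blank (uninoculated)
#' wells from every sample well, floors the result, and drops the blank
#' wells. With an empty blank list the data pass through unchanged (but the
#' curve is marked corrected).
#'
#' @param curve A [growth_curve()].
#' @param blank_wells Character vector of blank well ids (may be empty).
#' @param floor Minimum OD after subtraction (default 1e-3).
#' @return A blank-corrected `growth_curve` without the blank wells.
#' @examples
#' gc <- growth_curve(data.frame(
#'   time = rep(c(0, 1), 2), well = rep(c("S1", "B1"), each = 2),
#'   od = c(0.15, 0.30, 0.05, 0.05)))
#' blank_correct(gc, "B1")
#' @export
blank_correct <- function(curve, blank_wells = character(), floor = 1e-3) {
  stopifnot(inherits(curve, "growth_curve"))
  missing_wells <- setdiff(blank_wells, curve_wells(curve))
  if (length(missing_wells)) {
    abort(paste0("Blank well(s) not present: ",
                 paste(missing_wells, collapse = ", ")),
          class = "growthmedia_lookup_error")
  }
  if (length(blank_wells) == 0) {
    out <- curve
  } else {
    blanks <- dplyr::filter(curve, .data$well %in% blank_wells)
    blank_mean <- dplyr::summarise(dplyr::group_by(blanks, .data$time),
                                   blank_od = mean(.data$od), .groups = "drop")
    out <- curve |>
      dplyr::filter(!(.data$well %in% blank_wells)) |>
      dplyr::left_join(blank_mean, by = "time") |>
      dplyr::mutate(od = pmax(.data$od - .data$blank_od, floor)) |>
      dplyr::select(dplyr::all_of(c("time", "well", "od")))
  }
  meta <- attr(curve, "well_meta")
  if (!is.null(meta)) meta <- meta[!(meta$well %in% blank_wells), ]
  growth_curve(out, strain = attr(curve, "strain_label"),
               blank_corrected = TRUE, well_meta = meta)
}

#' Extract the wells of one strain from a multi-strain plate
#'
#' @param curve A [growth_curve()] whose `well_meta` carries a `strain`
#'   column (as produced by [generate_plate()]).
#' @param strain Strain label to keep.
#' @return A `growth_curve` restricted to that strain's wells.
#' @export
plate_strain <- function(curve, strain) {
  stopifnot(inherits(curve, "growth_curve"))
  meta <- attr(curve, "well_meta")
  if (is.null(meta) || !"strain" %in% names(meta)) {
    abort("Curve has no per-well strain metadata.",
          class = "growthmedia_lookup_error")
  }
  keep <- meta$well[!is.na(meta$strain) & meta$strain == strain]
  if (!length(keep)) {
    abort(paste0("No wells for strain ", strain, "."),
          class = "growthmedia_lookup_error")
  }
  growth_curve(dplyr::filter(curve, .data$well %in% keep),
               strain = strain,
               blank_corrected = attr(curve, "blank_corrected"),
               well_meta = meta[meta$well %in% keep, ])
}
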