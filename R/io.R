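# Plate-table readers/writers, result serialisation and run configuration.

#' Read a plate-reader table (wide or long CSV)
#'
#' Wide dialect: first column is time, every remaining column one well.
#' Long dialect: columns `time`, `well`, `od` (extra metadata columns are
#' carried along into `well_meta` if constant per well). Both dialects
#' produce identical internal data for equivalent content. Times must be
#' strictly increasing within each well; duplicated (well, time) pairs,
#' non-numeric ODs and ragged schedules are rejected with the offending
#' row/column named.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @param time_unit `"hours"` (default) or `"minutes"` (converted).
#' @param strain Optional strain label for the curve.
#' @return A [growth_curve()].
#' @export
read_plate_table <- function(path, dialect = c("wide", "long"),
                             time_unit = c("hours", "minutes"),
                             strain = NULL) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  if (dialect == "wide") {
    if (ncol(tab) < 2) {
      abort("Wide table needs a time column plus at least one well column.",
            class = "growthmedia_parse_error")
    }
    names(tab)[1] <- "time"
    for (cn in names(tab)) {
      if (!is.numeric(tab[[cn]])) {
        abort(paste0("Non-numeric values in column `", cn, "`."),
              class = "growthmedia_parse_error")
      }
    }
    long <- tidyr::pivot_longer(tab, -"time", names_to = "well",
                                values_to = "od")
  } else {
    need <- c("time", "well", "od")
    if (length(setdiff(need, names(tab)))) {
      abort("Long table needs `time`, `well`, `od` columns.",
            class = "growthmedia_parse_error")
    }
    for (cn in c("time", "od")) {
      if (!is.numeric(tab[[cn]])) {
        abort(paste0("Non-numeric values in column `", cn, "`."),
              class = "growthmedia_parse_error")
      }
    }
    long <- tab
  }
  if (anyNA(long$od) || anyNA(long$time)) {
    bad <- which(is.na(long$od) | is.na(long$time))[1]
    abort(paste0("Missing/unparseable value at data row ", bad, "."),
          class = "growthmedia_parse_error")
  }
  if (time_unit == "minutes") long$time <- long$time / 60
  meta_cols <- setdiff(names(long), c("time", "well", "od"))
  well_meta <- NULL
  if (length(meta_cols)) {
    well_meta <- dplyr::distinct(
      long[, c("well", meta_cols), drop = FALSE])
    if (anyDuplicated(well_meta$well)) {
      abort("Per-well metadata columns are not constant within wells.",
            class = "growthmedia_parse_error")
    }
  }
  growth_curve(long[, c("time", "well", "od")], strain = strain,
               well_meta = well_meta)
}

#' Write a growth curve as a plate table
#'
#' @param curve A [growth_curve()].
#' @param path Output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(curve, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(curve, "growth_curve"))
  if (dialect == "wide") {
    wide <- tidyr::pivot_wider(tibble::as_tibble(curve),
                               names_from = "well", values_from = "od")
    readr::write_csv(wide, path, progress = FALSE)
  } else {
    readr::write_csv(tibble::as_tibble(curve)[, c("time", "well", "od")],
                     path, progress = FALSE)
  }
  invisible(path)
}

#' Run configuration with the analysis defaults
#'
#' Collects the tunables of a full run; the defaults reproduce the
#' conventions the package is built around: natural-log BIC, five seeded
#' multi-starts, a 2-unit BIC tie margin favouring fewer parameters,
#' residuals on the raw OD scale, 0.01-h kinetics grid, competition
#' coefficients of 1, and 40/80% essentiality thresholds.
#'
#' @param ... Overrides of the default fields.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_starts = 5L,
    tie_margin = 2,
    residual_scale = "raw",
    blank_wells = character(),
    blank_floor = 1e-3,
    grid_step = 0.01,
    c1 = 1, c2 = 1,
    thresholds = c(40, 80),
    keep_overrides = character(),
    drop_overrides = character()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "growthmedia_config_error")
  }
  structure(modifyList(cfg, overrides), class = "run_config")
}

#' Write analysis results to an output directory
#'
#' Emits whichever result sets are supplied — `fits.csv` (one row per
#' model per curve), `kinetics.json`, `soe_calls.csv`,
#' `competition.csv` — plus `run_metadata.json` capturing the
#' configuration, and returns a manifest of written files.
#'
#' @param outdir Output directory (created if absent).
#' @param fits Optional `growth_fit_family` (or plain tibble of fit rows).
#' @param summaries Optional `kinetic_summary` tibble.
#' @param calls Optional SOE call tibble.
#' @param trajectories Optional `competition_trajectory`.
#' @param config Optional [run_config()] (recorded in the metadata).
#' @return Tibble manifest (`file`, `path`).
#' @export
write_results <- function(outdir, fits = NULL, summaries = NULL,
                          calls = NULL, trajectories = NULL,
                          config = run_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    abort(paste0("Cannot create output directory: ", outdir),
          class = "growthmedia_io_error")
  }
  manifest <- list()
  emit <- function(file) {
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(file = file, path = file.path(outdir, file))
    file.path(outdir, file)
  }
  if (!is.null(fits)) {
    rows <- tibble::as_tibble(fits)
    if ("fit" %in% names(rows)) {
      par_tab <- dplyr::bind_rows(lapply(rows$fit, function(f) {
        tibble::as_tibble(unclass(f$params))
      }))
      rows <- dplyr::bind_cols(rows[setdiff(names(rows), "fit")], par_tab)
    }
    readr::write_csv(rows, emit("fits.csv"), progress = FALSE)
  }
  if (!is.null(summaries)) {
    jsonlite::write_json(summaries, emit("kinetics.json"),
                         dataframe = "rows", digits = NA, auto_unbox = FALSE)
  }
  if (!is.null(calls)) {
    readr::write_csv(tibble::as_tibble(calls), emit("soe_calls.csv"),
                     progress = FALSE)
  }
  if (!is.null(trajectories)) {
    readr::write_csv(tibble::as_tibble(trajectories),
                     emit("competition.csv"), progress = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(config),
         written = vapply(manifest, function(m) m$file, character(1)),
         r_version = as.character(getRversion())),
    emit("run_metadata.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  dplyr::bind_rows(manifest)
}
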