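# Synthetic plate-reader and omission-experiment data with the statistical
# structure the analysis assumes, so every stage is testable offline.

#' Plate design for synthetic growth curves
#'
#' Describes a synthetic microtiter-plate run: sampling schedule, strain
#' groups (each a parameter set replicated over wells) and blank wells.
#' Defaults mirror the experimental design the analysis targets: 36 h at
#' 15-min intervals giving 144 readings per well (t = 0 to 35.75 h), 40
#' replicate wells per strain, 8 uninoculated blanks at a 0.05 OD
#' background.
#'
#' @param groups List of strain groups, each a list with `label`, `params`
#'   (a [growth_params()]) and `n_wells`.
#' @param duration Run length in hours.
#' @param interval Sampling interval in hours; `duration/interval` must be
#'   an integer (sampling runs from 0 to `duration - interval`).
#' @param blank_wells Number of blank wells.
#' @param blank_level Background OD added to every well.
#' @return A `plate_design` object.
#' @examples
#' d <- plate_design(groups = list(list(
#'   label = "demo", params = growth_params(0.1, 0.8, 1.2), n_wells = 3)))
#' @export
plate_design <- function(groups, duration = 36, interval = 0.25,
                         blank_wells = 8, blank_level = 0.05) {
  n_samples <- duration / interval
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("duration/interval must be an integer sample count.",
          class = "growthmedia_design_error")
  }
  for (g in groups) {
    if (!all(c("label", "params", "n_wells") %in% names(g)) ||
        !inherits(g$params, "growth_params") || g$n_wells < 1) {
      abort("Each group needs label, params (growth_params), n_wells >= 1.",
            class = "growthmedia_design_error")
    }
  }
  structure(
    list(groups = groups, duration = duration, interval = interval,
         blank_wells = blank_wells, blank_level = blank_level,
         n_samples = as.integer(round(n_samples))),
    class = "plate_design"
  )
}

#' Measurement-noise model for synthetic plates
#'
#' Additive and proportional Gaussian noise on each OD reading. The
#' additive default (sd 0.02 OD) reflects typical plate-reader
#' repeatability. Identical seeds give identical datasets.
#'
#' @param additive_sd Additive noise sd (OD, >= 0).
#' @param proportional_sd Proportional noise sd (dimensionless, >= 0).
#' @param seed Integer seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(additive_sd = 0.02, proportional_sd = 0, seed = 1L) {
  if (additive_sd < 0 || proportional_sd < 0) {
    abort("Noise sds must be >= 0.", class = "growthmedia_domain_error")
  }
  structure(list(additive_sd = additive_sd,
                 proportional_sd = proportional_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic plate-reader dataset
#'
#' Samples each group's closed-form growth curve on the design's schedule,
#' adds the blank background plus additive and proportional Gaussian
#' noise, floors readings at 0, and appends blank wells (background plus
#' noise only). Deterministic under the noise model's seed.
#'
#' @param design A [plate_design()].
#' @param noise A [noise_model()].
#' @return A [growth_curve()] whose `well_meta` attribute maps wells to
#'   strains (`NA` strain for blanks); blank well ids are in the
#'   `blank_wells` attribute.
#' @examples
#' d <- plate_design(groups = list(list(
#'   label = "demo", params = growth_params(0.1, 0.8, 1.2), n_wells = 2)),
#'   duration = 12, interval = 1, blank_wells = 1)
#' generate_plate(d, noise_model(seed = 7))
#' @export
generate_plate <- function(design, noise = noise_model()) {
  stopifnot(inherits(design, "plate_design"), inherits(noise, "noise_model"))
  times <- seq(0, by = design$interval, length.out = design$n_samples)
  with_preserved_seed(noise$seed, {
    blocks <- list()
    meta <- list()
    for (g in design$groups) {
      clean <- evaluate_growth(g$params, times)
      for (w in seq_len(g$n_wells)) {
        well <- sprintf("%s_w%02d", g$label, w)
        od <- clean + design$blank_level +
          rnorm(length(times), 0, noise$additive_sd) +
          clean * rnorm(length(times), 0, noise$proportional_sd)
        blocks[[well]] <- tibble::tibble(time = times, well = well,
                                         od = pmax(od, 0))
        meta[[well]] <- tibble::tibble(well = well, strain = g$label)
      }
    }
    blank_ids <- character()
    for (b in seq_len(design$blank_wells)) {
      well <- sprintf("blank_w%02d", b)
      blank_ids <- c(blank_ids, well)
      od <- design$blank_level + rnorm(length(times), 0, noise$additive_sd)
      blocks[[well]] <- tibble::tibble(time = times, well = well,
                                       od = pmax(od, 0))
      meta[[well]] <- tibble::tibble(well = well, strain = NA_character_)
    }
    out <- growth_curve(dplyr::bind_rows(blocks),
                        well_meta = dplyr::bind_rows(meta))
    attr(out, "blank_wells") <- blank_ids
    out
  })
}

#' Generate a synthetic single-omission dataset with known truth
#'
#' Draws each component's 24-h OD from a band matching its true class —
#' essential: 0-35%, stimulatory: 45-75%, non-essential: 85-115% of the
#' control OD (bands sit away from the 40/80 decision boundaries so labels
#' are recoverable) — plus additive noise; 0-h ODs sit near the inoculum
#' level.
#'
#' @param truth Named character vector mapping component names to
#'   `"essential"`, `"stimulatory"` or `"non_essential"`.
#' @param control_od Complete-medium 24-h control OD (> 0).
#' @param noise A [noise_model()]; its `additive_sd` is applied to the
#'   24-h ODs (in OD units).
#' @param strain Strain label for the observations.
#' @param inoculum_od Nominal 0-h OD.
#' @return A tibble (`omitted`, `strain`, `od_0h`, `od_24h`, `truth`).
#' @export
generate_soe_dataset <- function(truth, control_od, noise = noise_model(),
                                 strain = "synthetic",
                                 inoculum_od = 0.08) {
  if (!is.finite(control_od) || control_od <= 0) {
    abort("control_od must be > 0.", class = "growthmedia_domain_error")
  }
  bad <- setdiff(unique(truth), c("essential", "stimulatory",
                                  "non_essential"))
  if (length(bad)) {
    abort(paste0("Unknown truth class(es): ", paste(bad, collapse = ", ")),
          class = "growthmedia_domain_error")
  }
  bands <- list(essential = c(0, 0.35), stimulatory = c(0.45, 0.75),
                non_essential = c(0.85, 1.15))
  with_preserved_seed(noise$seed, {
    n <- length(truth)
    frac <- vapply(truth, function(cl) {
      runif(1, bands[[cl]][1], bands[[cl]][2])
    }, numeric(1))
    tibble::tibble(
      omitted = names(truth),
      strain = strain,
      od_0h = pmax(inoculum_od + rnorm(n, 0, noise$additive_sd / 2), 0),
      od_24h = pmax(frac * control_od + rnorm(n, 0, noise$additive_sd), 0),
      truth = unname(truth)
    )
  })
}
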