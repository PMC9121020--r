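# Defined-medium containers, minimal-medium composition from SOE calls,
# and the bundled chemically-defined-medium fixtures.

medium_groups <- c("carbon", "surfactant", "buffer_salt", "mineral",
                   "amino_acid", "nucleotide", "vitamin")

#' Defined-medium container
#'
#' A named set of medium components with group labels and concentrations.
#'
#' @param name Medium name.
#' @param components Data frame with columns `component`, `group` (one of
#'   carbon, surfactant, buffer_salt, mineral, amino_acid, nucleotide,
#'   vitamin) and `concentration` (g/L, > 0). Component names must be
#'   unique.
#' @return A `medium_definition` object.
#' @export
medium_definition <- function(name, components) {
  components <- tibble::as_tibble(components)
  need <- c("component", "group", "concentration")
  if (length(setdiff(need, names(components)))) {
    abort("components need `component`, `group`, `concentration` columns.",
          class = "growthmedia_parse_error")
  }
  if (anyDuplicated(components$component)) {
    abort("Component names must be unique.",
          class = "growthmedia_consistency_error")
  }
  if (any(!components$group %in% medium_groups)) {
    abort(paste0("Unknown group(s): ",
                 paste(setdiff(components$group, medium_groups),
                       collapse = ", ")),
          class = "growthmedia_parse_error")
  }
  if (any(!is.finite(components$concentration)) ||
      any(components$concentration <= 0)) {
    abort("Concentrations must be finite and > 0.",
          class = "growthmedia_parse_error")
  }
  structure(
    list(name = name, components = components[need]),
    class = "medium_definition"
  )
}

#' @export
print.medium_definition <- function(x, ...) {
  cat("<medium_definition> ", x$name, ": ", nrow(x$components),
      " components\n", sep = "")
  print(dplyr::count(x$components, .data$group))
  invisible(x)
}

#' Read / write a medium definition (TSV)
#'
#' Plain tab-separated files with columns `component`, `group`,
#' `concentration` (g/L).
#'
#' @param path File path.
#' @param name Medium name; defaults to the file stem.
#' @return [read_medium()] a `medium_definition`; [write_medium()] the
#'   path, invisibly.
#' @export
read_medium <- function(path, name = NULL) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  medium_definition(name %||% sub("\\.[^.]*$", "", basename(path)), tab)
}

#' @rdname read_medium
#' @param medium A `medium_definition`.
#' @export
write_medium <- function(medium, path) {
  stopifnot(inherits(medium, "medium_definition"))
  readr::write_tsv(medium$components, path, progress = FALSE)
  invisible(path)
}

#' Compose a minimal defined medium from essentiality calls
#'
#' Applies the omission logic: a component called essential or stimulatory
#' is retained (reincorporated), a component called non-essential is
#' dropped, and components without a call keep their place unless
#' explicitly dropped. Override sets make silent exceptions explicit:
#' `keep_overrides` are retained regardless of call, `drop_overrides` are
#' removed regardless of (absent) call. Concentrations are copied from the
#' source medium unchanged.
#'
#' @param cdm The complete medium ([medium_definition()]).
#' @param calls Data frame of essentiality calls for one strain with
#'   columns `component` (or `omitted`) and `call`. Every referenced
#'   component must exist in `cdm`; group pseudo-components must be
#'   filtered out first.
#' @param keep_overrides,drop_overrides Character vectors of component
#'   names (must exist in `cdm`).
#' @param name Name for the composed medium.
#' @return A `medium_definition` with the retained components.
#' @export
compose_minimal_medium <- function(cdm, calls,
                                   keep_overrides = character(),
                                   drop_overrides = character(),
                                   name = paste0("MDM(", cdm$name, ")")) {
  stopifnot(inherits(cdm, "medium_definition"))
  calls <- tibble::as_tibble(calls)
  if (!"component" %in% names(calls) && "omitted" %in% names(calls)) {
    calls$component <- calls$omitted
  }
  if (!all(c("component", "call") %in% names(calls))) {
    abort("calls need `component` (or `omitted`) and `call` columns.",
          class = "growthmedia_config_error")
  }
  comps <- cdm$components$component
  stray <- setdiff(c(calls$component, keep_overrides, drop_overrides), comps)
  if (length(stray)) {
    abort(paste0("Not in the source medium: ",
                 paste(stray, collapse = ", ")),
          class = "growthmedia_consistency_error")
  }
  both <- intersect(keep_overrides, drop_overrides)
  if (length(both)) {
    abort(paste0("Component(s) in both override sets: ",
                 paste(both, collapse = ", ")),
          class = "growthmedia_consistency_error")
  }
  call_of <- setNames(calls$call, calls$component)
  keep <- vapply(comps, function(cp) {
    if (cp %in% keep_overrides) return(TRUE)
    if (cp %in% drop_overrides) return(FALSE)
    if (cp %in% names(call_of)) {
      return(call_of[[cp]] %in% c("essential", "stimulatory"))
    }
    TRUE  # no call: core component, kept
  }, logical(1))
  medium_definition(name, cdm$components[keep, ])
}

#' Union of two media (co-culture medium)
#'
#' Set union of the component lists; commutative and idempotent. A
#' component present in both media must have the same concentration.
#'
#' @param a,b `medium_definition` objects.
#' @param name Name for the union.
#' @return A `medium_definition`.
#' @export
union_medium <- function(a, b, name = paste0(a$name, "+", b$name)) {
  stopifnot(inherits(a, "medium_definition"),
            inherits(b, "medium_definition"))
  shared <- dplyr::inner_join(a$components, b$components,
                              by = "component", suffix = c("_a", "_b"))
  bad <- shared[shared$concentration_a != shared$concentration_b, ]
  if (nrow(bad)) {
    abort(paste0("Conflicting concentrations for: ",
                 paste(bad$component, collapse = ", ")),
          class = "growthmedia_consistency_error")
  }
  extra <- b$components[!(b$components$component %in%
                            a$components$component), ]
  medium_definition(name, dplyr::bind_rows(a$components, extra))
}

# ---- bundled fixtures ------------------------------------------------------

fixture_path <- function(file) {
  system.file("extdata", file, package = "growthmedia", mustWork = TRUE)
}

#' Bundled chemically defined medium and omission-table fixtures
#'
#' `cdm_medium()` returns the 49-component complete chemically defined
#' medium; `mdm_medium()` the published minimal media for *L. salivarius*
#' ZJ614 (`"ls"`), *L. reuteri* ZJ625 (`"lr"`) or their co-culture union
#' (`"lslr"`). `soe_table()` returns the published 37-row single-omission
#' table in long form (74 strain x omission records) with printed relative
#' growth and calls; rows 1-3 are whole-group omissions
#' (`is_group = TRUE`) whose calls never drive medium composition.
#' `mdm_overrides()` returns the documented exception sets used when the
#' minimal media were composed: cysteine kept despite a non-essential
#' call, six trace minerals dropped without omission rows.
#'
#' @param which Which minimal medium to load.
#' @return See Description.
#' @export
cdm_medium <- function() {
  read_medium(fixture_path("cdm.tsv"), name = "CDM")
}

#' @rdname cdm_medium
#' @export
mdm_medium <- function(which = c("ls", "lr", "lslr")) {
  which <- match.arg(which)
  read_medium(fixture_path(paste0("mdm_", which, ".tsv")),
              name = paste0("MDM", toupper(which)))
}

#' @rdname cdm_medium
#' @export
soe_table <- function() {
  wide <- readr::read_csv(fixture_path("soe_table3.csv"), comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  long <- dplyr::bind_rows(
    dplyr::transmute(wide,
      s_no = .data$s_no, omitted = .data$omitted,
      component = .data$component, is_group = .data$is_group,
      strain = "ZJ614", od_0h = .data$od_0h_zj614,
      od_24h = .data$od_24h_zj614,
      relative_growth_pct = .data$relative_growth_zj614,
      call_printed = .data$call_zj614),
    dplyr::transmute(wide,
      s_no = .data$s_no, omitted = .data$omitted,
      component = .data$component, is_group = .data$is_group,
      strain = "ZJ625", od_0h = .data$od_0h_zj625,
      od_24h = .data$od_24h_zj625,
      relative_growth_pct = .data$relative_growth_zj625,
      call_printed = .data$call_zj625)
  )
  dplyr::arrange(long, .data$s_no, .data$strain)
}

#' @rdname cdm_medium
#' @export
mdm_overrides <- function() {
  list(
    keep = "L-Cysteine",
    drop = c("CoCl2.6H2O", "CaCl2.2H2O", "ZnSO4.7H2O", "H3BO3", "KCl",
             "CuSO4.5H2O")
  )
}

#' Compose the published minimal medium for one strain
#'
#' Convenience wrapper: classifies the bundled omission table with the
#' printed relative-growth values, drops the group pseudo-components, and
#' composes the minimal medium with the documented override sets.
#'
#' @param strain `"ZJ614"` or `"ZJ625"`.
#' @return A `medium_definition`.
#' @export
compose_published_mdm <- function(strain = c("ZJ614", "ZJ625")) {
  strain <- match.arg(strain)
  soe <- dplyr::filter(soe_table(), .data$strain == !!strain, !.data$is_group)
  calls <- analyze_soe_table(soe)
  calls$component <- soe$component
  ov <- mdm_overrides()
  compose_minimal_medium(cdm_medium(), calls,
                         keep_overrides = ov$keep,
                         drop_overrides = ov$drop,
                         name = if (strain == "ZJ614") "MDMLS" else "MDMLR")
}
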