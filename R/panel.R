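# Panel configuration: analyte constants, validation-design constants, and
# the default 15-analyte sulphonamide/dapsone/trimethoprim milk panel.

#' Construct the validation-design constants
#'
#' Bundles the constants of the EU screening-validation design: cohort sizes,
#' the SD multipliers used by the threshold `T` and the cut-off factor `Fm`,
#' the maximum number of false-compliant spiked controls tolerated by the
#' detection-capability decision, the target false-compliant rate beta, and
#' the sample dilution factor applied during preparation (milk diluted 1:1
#' with wash buffer, i.e. factor 2).
#'
#' @param n_blank Number of blank (analyte-free) control samples per analyte.
#' @param n_spiked Number of spiked (screen-positive) control samples per
#'   analyte.
#' @param t_factor SD multiplier in `T = mean(blank) - t_factor * sd(blank)`.
#' @param fm_factor SD multiplier in `Fm = mean(spiked) + fm_factor *
#'   sd(spiked)`; 1.64 is the one-sided 5% normal quantile.
#' @param max_false_compliant Largest number of spiked controls allowed to
#'   screen negative while still declaring the spike level validated
#'   (CCbeta = spike level).
#' @param beta Target false-compliant rate of the screening design.
#' @param dilution_factor Sample dilution applied before measurement; used
#'   only when back-calculating concentrations from RLU.
#'
#' @return An object of class `validation_config` (a named list).
#' @export
#' @examples
#' validation_config()
validation_config <- function(n_blank = 20, n_spiked = 20,
                              t_factor = 1.6, fm_factor = 1.64,
                              max_false_compliant = 1, beta = 0.05,
                              dilution_factor = 2) {
  cfg <- list(
    n_blank = as.integer(n_blank), n_spiked = as.integer(n_spiked),
    t_factor = as.numeric(t_factor), fm_factor = as.numeric(fm_factor),
    max_false_compliant = as.integer(max_false_compliant),
    beta = as.numeric(beta), dilution_factor = as.numeric(dilution_factor)
  )
  if (cfg$n_blank < 2L || cfg$n_spiked < 2L)
    stop("validation_config: n_blank and n_spiked must each be >= 2 (SD undefined otherwise)")
  if (cfg$t_factor <= 0 || cfg$fm_factor <= 0)
    stop("validation_config: t_factor and fm_factor must be > 0")
  if (cfg$dilution_factor < 1)
    stop("validation_config: dilution_factor must be >= 1")
  if (cfg$max_false_compliant >= cfg$n_spiked)
    stop("validation_config: max_false_compliant must be < n_spiked")
  if (cfg$beta <= 0 || cfg$beta >= 1)
    stop("validation_config: beta must lie in (0, 1)")
  structure(cfg, class = "validation_config")
}

#' Construct one analyte's regulatory and assay constants
#'
#' @param name Short analyte code (e.g. `"SDZ"`).
#' @param full_name Full analyte name.
#' @param mrl Maximum residue limit in ug/kg; `NA` for prohibited substances.
#' @param prohibited Logical; `TRUE` for substances with no MRL (any
#'   confirmed presence is non-compliant).
#' @param spike_level Concentration in ug/kg at which positive controls are
#'   fortified; must not exceed the MRL for non-prohibited analytes.
#' @param calib_min,calib_max Calibration range in ug/kg, as supplied with
#'   the assay (the range already accounts for the sample dilution factor).
#' @param lod Limit of detection in ug/kg.
#' @param screening_target Concentration in ug/kg screened for when no MRL
#'   exists; required iff `prohibited` is `TRUE`.
#'
#' @return A one-row [tibble::tibble()] with one column per field.
#' @export
#' @examples
#' analyte_spec("SDZ", "Sulphadiazine", mrl = 100, spike_level = 20,
#'              calib_min = 0, calib_max = 40, lod = 0.5)
analyte_spec <- function(name, full_name = name, mrl = NA_real_,
                         prohibited = FALSE, spike_level,
                         calib_min = 0, calib_max, lod,
                         screening_target = NA_real_) {
  spec <- tibble::tibble(
    name = as.character(name), full_name = as.character(full_name),
    mrl = as.numeric(mrl), prohibited = isTRUE(prohibited),
    spike_level = as.numeric(spike_level),
    calib_min = as.numeric(calib_min), calib_max = as.numeric(calib_max),
    lod = as.numeric(lod), screening_target = as.numeric(screening_target)
  )
  validate_analyte_spec(spec)
  spec
}

validate_analyte_spec <- function(spec) {
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    who <- s$name
    if (!nzchar(who)) stop("analyte_spec: empty analyte name")
    if (!is.finite(s$spike_level) || s$spike_level <= 0)
      stop(sprintf("analyte_spec [%s]: spike_level must be > 0", who))
    if (!is.finite(s$calib_min) || s$calib_min < 0)
      stop(sprintf("analyte_spec [%s]: calib_min must be >= 0", who))
    if (!is.finite(s$calib_max) || s$calib_max <= s$calib_min)
      stop(sprintf("analyte_spec [%s]: calib_max must be > calib_min", who))
    if (!is.finite(s$lod) || s$lod >= s$spike_level)
      stop(sprintf("analyte_spec [%s]: lod must be < spike_level", who))
    if (s$spike_level > s$calib_max)
      stop(sprintf("analyte_spec [%s]: spike_level must be <= calib_max", who))
    if (s$prohibited) {
      if (is.finite(s$mrl))
        stop(sprintf("analyte_spec [%s]: prohibited substances have no MRL", who))
      if (!is.finite(s$screening_target))
        stop(sprintf("analyte_spec [%s]: prohibited substances need a screening_target", who))
    } else {
      if (!is.finite(s$mrl))
        stop(sprintf("analyte_spec [%s]: mrl is required for non-prohibited analytes", who))
      if (s$spike_level > s$mrl)
        stop(sprintf("analyte_spec [%s]: spike_level (%g) must be <= mrl (%g)",
                     who, s$spike_level, s$mrl))
    }
  }
  invisible(spec)
}

#' Assemble a panel configuration
#'
#' @param analytes A tibble of analyte rows as produced by [analyte_spec()]
#'   (rows may be bound together).
#' @param validation A [validation_config()].
#' @param sulphonamide_members Character vector of analyte names whose
#'   concentrations sum toward the sulphonamide group MRL.
#' @param sulphonamide_sum_mrl Group MRL in ug/kg for the summed
#'   sulphonamides (100 ug/kg in milk).
#'
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(analytes, validation = validation_config(),
                         sulphonamide_members = character(),
                         sulphonamide_sum_mrl = 100) {
  validate_analyte_spec(analytes)
  if (anyDuplicated(analytes$name))
    stop("panel_config: duplicate analyte name: ",
         paste(unique(analytes$name[duplicated(analytes$name)]), collapse = ", "))
  if (!inherits(validation, "validation_config"))
    validation <- do.call(validation_config, as.list(validation))
  bad <- setdiff(sulphonamide_members, analytes$name)
  if (length(bad))
    stop("panel_config: sulphonamide_members not in panel: ",
         paste(bad, collapse = ", "))
  structure(list(
    analytes = analytes,
    validation = validation,
    sulphonamide_members = as.character(sulphonamide_members),
    sulphonamide_sum_mrl = as.numeric(sulphonamide_sum_mrl)
  ), class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> %d analytes (%d sulphonamides, sum MRL %g ug/kg)\n",
              nrow(x$analytes), length(x$sulphonamide_members),
              x$sulphonamide_sum_mrl))
  cat(sprintf("  validation: %d blank + %d spiked, T = mean - %g SD, Fm = mean + %g SD,\n",
              x$validation$n_blank, x$validation$n_spiked,
              x$validation$t_factor, x$validation$fm_factor))
  cat(sprintf("  <= %d false compliant allowed, dilution factor %g\n",
              x$validation$max_false_compliant, x$validation$dilution_factor))
  print(x$analytes, n = nrow(x$analytes))
  invisible(x)
}

#' The default 15-analyte milk screening panel
#'
#' The biochip multi-array milk panel: 13 sulphonamides, dapsone (DAP, a
#' prohibited substance screened at 20 ug/kg) and trimethoprim (TMPM, MRL
#' 50 ug/kg). MRLs, calibration ranges (already accounting for the 1:1
#' wash-buffer dilution, factor 2) and chosen spike levels are the kit's
#' validated constants; LODs are the manufacturer's. All sulphonamide spike
#' levels sit at or below half the 100 ug/kg group MRL.
#'
#' @return A [panel_config()] with 15 analytes, 13 of them sulphonamide
#'   group members.
#' @export
#' @examples
#' p <- default_panel()
#' nrow(p$analytes)
default_panel <- function() {
  a <- dplyr::bind_rows(
    analyte_spec("SDZ",  "Sulphadiazine",           100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("SDIM", "Sulphadimethoxine",       100, FALSE, 20, 0,  40, 0.6),
    analyte_spec("SQX",  "Sulphaquinoxaline",       100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("SMTZ", "Sulphamethazine",         100, FALSE, 20, 0,  40, 2.5),
    analyte_spec("SMXZ", "Sulphamethoxazole",       100, FALSE, 12, 0,  25, 0.5),
    analyte_spec("STZ",  "Sulphathiazole",          100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("SSX",  "Sulphisoxazole",          100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("SPD",  "Sulphapyridine",          100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("SMZ",  "Sulphamerazine",          100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("SMMX", "Sulphamonomethoxine",     100, FALSE, 50, 0, 240, 2),
    analyte_spec("SMPD", "Sulphamethoxypyridazine", 100, FALSE, 20, 0,  40, 2),
    analyte_spec("SCPD", "Sulphachlorpyridazine",   100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("DAP",  "Dapsone", NA, TRUE,           20, 0,  40, 0.5,
                 screening_target = 20),
    analyte_spec("SDX",  "Sulphadoxine",            100, FALSE, 20, 0,  40, 0.5),
    analyte_spec("TMPM", "Trimethoprim",             50, FALSE, 10, 0,  20, 0.5)
  )
  panel_config(
    analytes = a,
    validation = validation_config(),
    sulphonamide_members = setdiff(a$name, c("DAP", "TMPM")),
    sulphonamide_sum_mrl = 100
  )
}

panel_to_list <- function(panel) {
  list(
    analytes = lapply(seq_len(nrow(panel$analytes)), function(i) {
      s <- as.list(panel$analytes[i, ])
      # drop NA optional fields so the document stays minimal
      if (!is.finite(s$mrl)) s$mrl <- NULL
      if (!is.finite(s$screening_target)) s$screening_target <- NULL
      s
    }),
    validation = unclass(panel$validation),
    sulphonamide_members = panel$sulphonamide_members,
    sulphonamide_sum_mrl = panel$sulphonamide_sum_mrl
  )
}

#' Serialize a panel configuration to YAML or JSON
#'
#' @param panel A [panel_config()].
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_config"))
  doc <- panel_to_list(panel)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

#' Load a panel configuration from a YAML or JSON document
#'
#' Unspecified validation fields take the [validation_config()] defaults;
#' all panel invariants are enforced, with errors naming the offending
#' analyte and field.
#'
#' @param path Path to a YAML or JSON panel document (schema as written by
#'   [write_panel()]).
#' @return A [panel_config()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("load_panel: no such file: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$analytes) || !length(doc$analytes))
    stop("load_panel: document has no 'analytes' section")
  analytes <- dplyr::bind_rows(lapply(doc$analytes, function(s) {
    if (is.null(s$name)) stop("load_panel: analyte entry without 'name'")
    required <- c("spike_level", "calib_max", "lod")
    missing <- required[!required %in% names(s)]
    if (length(missing))
      stop(sprintf("load_panel [%s]: missing field(s): %s",
                   s$name, paste(missing, collapse = ", ")))
    analyte_spec(
      name = s$name,
      full_name = s$full_name %||% s$name,
      mrl = s$mrl %||% NA_real_,
      prohibited = isTRUE(s$prohibited),
      spike_level = s$spike_level,
      calib_min = s$calib_min %||% 0,
      calib_max = s$calib_max,
      lod = s$lod,
      screening_target = s$screening_target %||% NA_real_
    )
  }))
  val <- do.call(validation_config, as.list(doc$validation %||% list()))
  panel_config(
    analytes = analytes,
    validation = val,
    sulphonamide_members = unlist(doc$sulphonamide_members) %||% character(),
    sulphonamide_sum_mrl = doc$sulphonamide_sum_mrl %||% 100
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up one analyte's row in a panel
#'
#' @param panel A [panel_config()].
#' @param name Analyte code.
#' @return A one-row tibble.
#' @export
panel_analyte <- function(panel, name) {
  i <- match(name, panel$analytes$name)
  if (is.na(i)) stop("panel_analyte: unknown analyte: ", name)
  panel$analytes[i, ]
}
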