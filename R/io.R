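# File formats and report rendering: plain-CSV sample tables, JSON reports
# with embedded run manifests, and human-readable table renderings.

#' Build a run manifest
#'
#' A small provenance record embedded in every pipeline output so any run
#' can be reproduced from its own files.
#'
#' @param command Pipeline stage name (`"simulate"`, `"validate"`,
#'   `"screen"`, ...).
#' @param seed Seed used, if any.
#' @param panel Panel file path or `"default"`.
#' @param inputs,outputs Character vectors of file paths.
#' @param overrides Named list of non-default parameter values.
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(command, seed = NULL, panel = "default",
                         inputs = character(), outputs = character(),
                         overrides = list()) {
  structure(list(
    tool = "milkscreen",
    version = as.character(utils::packageVersion("milkscreen")),
    command = command,
    seed = seed,
    panel = panel,
    inputs = inputs,
    outputs = outputs,
    overrides = overrides,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write a sample-record table to CSV
#'
#' One row per measurement with the documented header `sample_id, analyte,
#' rlu, cohort, true_conc, milk_type, seed_meta`. A manifest, when given, is
#' written alongside as `<path>.manifest.json`.
#'
#' @param records Sample-record tibble.
#' @param path Output CSV path.
#' @param manifest Optional [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_samples <- function(records, path, manifest = NULL) {
  out <- records
  # fixed six-decimal formatting keeps write -> read -> write byte-stable
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- formatC(out[[col]], format = "f", digits = 6)
  readr::write_csv(out, path)
  if (!is.null(manifest))
    jsonlite::write_json(unclass(manifest), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a sample-record table from CSV
#'
#' @param path CSV path as written by [write_samples()] (or hand-built with
#'   at least `sample_id`, `analyte`, `rlu`, `cohort`).
#' @return A sample-record tibble.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("read_samples: no such file: ", path)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "analyte", "rlu", "cohort")
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop("read_samples: missing column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(out$rlu))
    stop("read_samples: column 'rlu' must be numeric")
  out
}

#' Write a validation report to JSON
#'
#' @param report A `validation_report` from [validate_panel()].
#' @param path Output JSON path.
#' @param manifest Optional [run_manifest()]; an existing `report$manifest`
#'   is reused so that write/read/write round-trips are byte-stable.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path, manifest = NULL) {
  stopifnot(inherits(report, "validation_report"))
  doc <- list(
    kind = "validation_report",
    manifest = unclass(manifest %||% report$manifest),
    cutoffs = report$cutoffs,
    errors = report$errors,
    ccbeta = report$ccbeta,
    summary = report$summary
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a validation report from JSON
#'
#' @param path JSON path written by [write_validation_report()].
#' @return A `validation_report` (with its manifest, when present, under
#'   `$manifest`).
#' @export
read_validation_report <- function(path) {
  if (!file.exists(path)) stop("read_validation_report: no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$kind, "validation_report"))
    stop("read_validation_report: not a validation report: ", path)
  rep <- structure(list(
    cutoffs = tibble::as_tibble(doc$cutoffs),
    errors = tibble::as_tibble(doc$errors),
    ccbeta = tibble::as_tibble(doc$ccbeta),
    summary = doc$summary
  ), class = "validation_report")
  if (is.na(rep$ccbeta$cc_beta[1]) && !is.numeric(rep$ccbeta$cc_beta))
    rep$ccbeta$cc_beta <- as.numeric(rep$ccbeta$cc_beta)
  if (!is.null(doc$manifest)) rep$manifest <- doc$manifest
  rep
}

#' Write a survey report to JSON
#'
#' @param report A `survey_report` from [survey_summary()].
#' @param path Output JSON path.
#' @param manifest Optional [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_survey_report <- function(report, path, manifest = NULL) {
  stopifnot(inherits(report, "survey_report"))
  doc <- list(
    kind = "survey_report",
    manifest = unclass(manifest %||% report$manifest),
    n_samples = report$n_samples,
    per_analyte = report$per_analyte,
    per_sample = report$per_sample,
    summary = report$summary
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a survey report from JSON
#'
#' @param path JSON path written by [write_survey_report()].
#' @return A `survey_report`.
#' @export
read_survey_report <- function(path) {
  if (!file.exists(path)) stop("read_survey_report: no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$kind, "survey_report"))
    stop("read_survey_report: not a survey report: ", path)
  rep <- structure(list(
    n_samples = doc$n_samples,
    per_analyte = tibble::as_tibble(doc$per_analyte),
    per_sample = tibble::as_tibble(doc$per_sample),
    summary = doc$summary
  ), class = "survey_report")
  if (!is.null(doc$manifest)) rep$manifest <- doc$manifest
  rep
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

# Truncate (floor) to `digits` decimals, the convention of the survey table
# (1 positive of 53 prints as 1.88%).
fmt_trunc <- function(x, digits = 2) {
  formatC(floor(x * 10^digits) / 10^digits, format = "f", digits = digits)
}

render_wide <- function(label, values) {
  paste(formatC(label, width = 24, flag = "-"),
        paste(formatC(values, width = 9), collapse = " "))
}

#' Render a validation report as text tables
#'
#' Produces the summary layout of a screening validation: per-analyte spike
#' concentration, T, Fm, the T > Fm check and error counts under the chosen
#' rule, followed by the error comparison under both cut-off choices and
#' the CCbeta decisions.
#'
#' @param report A `validation_report`.
#' @param panel Optional [panel_config()] (adds spike levels to the header).
#' @return Character vector of lines.
#' @export
render_validation_report <- function(report, panel = NULL) {
  co <- report$cutoffs
  err <- function(rule, col) {
    e <- report$errors[report$errors$cutoff_rule == rule, ]
    e[match(co$analyte, e$analyte), ][[col]]
  }
  rule <- report$summary$cutoff_rule
  lines <- c(
    sprintf("Validation summary (cut-off rule: %s)", rule),
    render_wide("", co$analyte)
  )
  if (!is.null(panel)) {
    sp <- panel$analytes$spike_level[match(co$analyte, panel$analytes$name)]
    lines <- c(lines, render_wide("Concentration (ug/kg)", fmt_num(sp, 0)))
  }
  lines <- c(
    lines,
    render_wide("T value (RLU)", fmt_num(co$t_value)),
    render_wide("Fm value (RLU)", fmt_num(co$fm_value)),
    render_wide("T > Fm", ifelse(co$valid, "Yes", "No")),
    render_wide("Number of FP", err(rule, "false_positive")),
    render_wide("FP rate (%)", fmt_num(err(rule, "fp_rate"), 0)),
    render_wide("Number of FN", err(rule, "false_negative")),
    render_wide("FN rate (%)", fmt_num(err(rule, "fn_rate"), 0)),
    "",
    "Errors under either cut-off choice:",
    render_wide("", co$analyte),
    render_wide("Cut-off = T: FP", err("T", "false_positive")),
    render_wide("Cut-off = T: FN", err("T", "false_negative")),
    render_wide("Cut-off = Fm: FP", err("Fm", "false_positive")),
    render_wide("Cut-off = Fm: FN", err("Fm", "false_negative")),
    "",
    "Detection capabilities:",
    render_wide("", report$ccbeta$analyte),
    render_wide("Spike level (ug/kg)", fmt_num(report$ccbeta$spike_level, 0)),
    render_wide("Decision", report$ccbeta$decision),
    render_wide("CCbeta (ug/kg)",
                ifelse(is.na(report$ccbeta$cc_beta), "-",
                       fmt_num(report$ccbeta$cc_beta, 0)))
  )
  lines
}

#' Render a survey report as a text table
#'
#' Occurrence table over the screened cohort: per analyte the number of
#' samples, the cut-off used, the positive count and the positive
#' percentage (truncated to two decimals, the source table's convention).
#'
#' @param report A `survey_report`.
#' @return Character vector of lines.
#' @export
render_survey_report <- function(report) {
  pa <- report$per_analyte
  c(
    "Survey screening summary",
    render_wide("Parameters", pa$analyte),
    render_wide("Number of samples", rep(report$n_samples, nrow(pa))),
    render_wide("Cut-off", fmt_num(pa$cutoff)),
    render_wide("Number of positive", pa$n_positive),
    render_wide("%Positive samples (%)", fmt_trunc(pa$pct_positive)),
    "",
    sprintf("Compliant samples: %d of %d (%s%%)",
            report$summary$n_compliant, report$n_samples,
            fmt_trunc(report$summary$pct_compliant))
  )
}
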