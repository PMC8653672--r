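# Survey screening: per-analyte calls against the chosen cut-offs, optional
# concentration back-calculation, and MRL-compliance summaries.

#' Screen survey records against per-analyte cut-offs
#'
#' Each record is called `"positive"` when its RLU lies strictly below the
#' analyte's cut-off (competitive format), `"negative"` otherwise. When a
#' calibration model is supplied for an analyte, the sample concentration is
#' back-calculated as `inverse_signal(rlu) * dilution_factor`; saturated
#' signals (at or below the curve floor) are censored as `NA` with flag
#' `"above_range"` rather than given a fabricated number.
#'
#' @param records Survey sample records (`sample_id`, `analyte`, `rlu`).
#' @param cutoffs Named numeric vector of cut-offs (RLU) covering every
#'   analyte present in `records`, or a `validation_report` whose chosen
#'   cut-offs are used.
#' @param models Optional named list of [calibration_model()]s; analytes
#'   without a model get `est_conc = NA` and flag `"no_model"`.
#' @param dilution_factor Dilution applied during sample preparation,
#'   multiplied back into estimated concentrations (default 2).
#' @return A tibble with one row per input record: `sample_id`, `analyte`,
#'   `rlu`, `cutoff`, `call`, `est_conc`, `conc_flag`.
#' @export
screen_samples <- function(records, cutoffs, models = NULL,
                           dilution_factor = 2) {
  if (inherits(cutoffs, "validation_report"))
    cutoffs <- stats::setNames(cutoffs$cutoffs$chosen_cutoff,
                               cutoffs$cutoffs$analyte)
  analytes <- unique(records$analyte)
  missing <- setdiff(analytes, names(cutoffs))
  if (length(missing))
    stop("screen_samples: no cut-off for analyte(s): ",
         paste(missing, collapse = ", "))
  out <- tibble::tibble(
    sample_id = records$sample_id,
    analyte = records$analyte,
    rlu = records$rlu,
    cutoff = unname(cutoffs[records$analyte]),
    call = NA_character_,
    est_conc = NA_real_,
    conc_flag = "no_model"
  )
  out$call <- classify_rlu(out$rlu, out$cutoff)
  if (!is.null(models)) {
    for (a in intersect(analytes, names(models))) {
      idx <- which(out$analyte == a)
      inv <- inverse_signal(out$rlu[idx], models[[a]])
      out$est_conc[idx] <- inv$conc * dilution_factor
      out$conc_flag[idx] <- inv$flag
    }
  }
  out
}

#' Summarize a screened survey cohort
#'
#' Per-analyte positive counts and percentages over the cohort, per-sample
#' compliance (a sample is compliant iff it screens negative for every
#' analyte), and — when concentrations are available — the summed
#' sulphonamide concentration per sample compared against the group MRL.
#'
#' @param screening Output of [screen_samples()].
#' @param panel A [panel_config()].
#' @return An object of class `survey_report`: a list with `n_samples`,
#'   tibble `per_analyte` (`analyte`, `cutoff`, `n_positive`,
#'   `pct_positive` — exact percentage), tibble `per_sample` (`sample_id`,
#'   `n_positive_calls`, `compliant`, `sulphonamide_sum`,
#'   `sulphonamide_sum_ok`), and a `summary` list (`n_compliant`,
#'   `pct_compliant`).
#' @export
survey_summary <- function(screening, panel) {
  stopifnot(inherits(panel, "panel_config"))
  if (!nrow(screening)) stop("survey_summary: empty screening table")
  samples <- unique(screening$sample_id)
  n_samples <- length(samples)

  per_analyte <- screening |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      cutoff = .data$cutoff[1],
      n_positive = sum(.data$call == "positive"),
      pct_positive = 100 * sum(.data$call == "positive") / n_samples,
      .groups = "drop"
    )
  # keep panel order
  per_analyte <- per_analyte[order(match(per_analyte$analyte,
                                         panel$analytes$name)), ]

  sul <- panel$sulphonamide_members
  per_sample <- screening |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_positive_calls = sum(.data$call == "positive"),
      compliant = all(.data$call == "negative"),
      sulphonamide_sum = if (all(is.na(.data$est_conc[.data$analyte %in% sul])))
        NA_real_
      else
        sum(.data$est_conc[.data$analyte %in% sul], na.rm = TRUE),
      .groups = "drop"
    )
  per_sample$sulphonamide_sum_ok <-
    ifelse(is.na(per_sample$sulphonamide_sum), NA,
           per_sample$sulphonamide_sum <= panel$sulphonamide_sum_mrl)

  structure(list(
    n_samples = n_samples,
    per_analyte = per_analyte,
    per_sample = per_sample,
    summary = list(
      n_compliant = sum(per_sample$compliant),
      pct_compliant = 100 * sum(per_sample$compliant) / n_samples
    )
  ), class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat(sprintf("<survey_report> %d samples, %d compliant (%.2f%%)\n",
              x$n_samples, x$summary$n_compliant, x$summary$pct_compliant))
  print(x$per_analyte, n = nrow(x$per_analyte))
  invisible(x)
}
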