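# Screening-validation statistics: threshold T, cut-off factor Fm, sample
# classification, error accounting under either cut-off choice, and the
# detection-capability (CCbeta) decision.

insufficient <- function(what, n) {
  stop(sprintf("%s: need at least 2 values, got %d", what, n))
}

#' Threshold T from blank signals
#'
#' `T = mean(blank RLU) - t_factor * sd(blank RLU)`, the lower validity
#' bound derived from the analyte-free controls. The SD is the sample SD
#' (n - 1 denominator).
#'
#' @param blank_rlus Numeric vector of blank-control signals (>= 2 values).
#' @param t_factor SD multiplier (default 1.6).
#' @return The threshold in RLU.
#' @export
#' @examples
#' threshold_t(c(4000, 4200, 3800, 4000))
threshold_t <- function(blank_rlus, t_factor = 1.6) {
  if (length(blank_rlus) < 2) insufficient("threshold_t", length(blank_rlus))
  mean(blank_rlus) - t_factor * stats::sd(blank_rlus)
}

#' Cut-off factor Fm from spiked signals
#'
#' `Fm = mean(spiked RLU) + fm_factor * sd(spiked RLU)`, the decision
#' boundary derived from the screen-positive controls; 1.64 is the
#' one-sided 5% normal quantile, targeting a 5% false-compliant rate.
#'
#' @param spiked_rlus Numeric vector of spiked-control signals (>= 2 values).
#' @param fm_factor SD multiplier (default 1.64).
#' @return The cut-off in RLU.
#' @export
#' @examples
#' cutoff_fm(c(300, 350, 250, 300))
cutoff_fm <- function(spiked_rlus, fm_factor = 1.64) {
  if (length(spiked_rlus) < 2) insufficient("cutoff_fm", length(spiked_rlus))
  mean(spiked_rlus) + fm_factor * stats::sd(spiked_rlus)
}

#' Classify a signal against a cut-off
#'
#' Competitive format: a sample screens positive when its signal is strictly
#' below the cut-off; a signal exactly at the cut-off screens negative.
#'
#' @param rlu Signal value(s) in RLU.
#' @param cutoff Cut-off in RLU.
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
classify_rlu <- function(rlu, cutoff) {
  if (any(!is.finite(cutoff))) stop("classify_rlu: cutoff must be finite")
  ifelse(rlu < cutoff, "positive", "negative")
}

#' Count false positives and false negatives at a cut-off
#'
#' False positives are blank controls that screen positive (RLU below the
#' cut-off); false negatives are spiked controls that screen negative (RLU
#' at or above the cut-off). Rates are percentages of the cohort sizes.
#'
#' @param blank_rlus,spiked_rlus Numeric vectors of control signals.
#' @param cutoff Cut-off in RLU.
#' @param rule_label Which rule produced the cut-off: `"T"` or `"Fm"`.
#' @param analyte Optional analyte code carried into the result.
#' @return A one-row tibble with columns `analyte`, `cutoff_rule`, `cutoff`,
#'   `n_blank`, `n_spiked`, `false_positive`, `false_negative`, `fp_rate`,
#'   `fn_rate`.
#' @export
count_errors <- function(blank_rlus, spiked_rlus, cutoff,
                         rule_label = c("Fm", "T"), analyte = NA_character_) {
  rule_label <- match.arg(rule_label)
  if (!length(blank_rlus)) insufficient("count_errors (blank)", 0L)
  if (!length(spiked_rlus)) insufficient("count_errors (spiked)", 0L)
  if (!is.finite(cutoff)) stop("count_errors: cutoff must be finite")
  fp <- sum(classify_rlu(blank_rlus, cutoff) == "positive")
  fn <- sum(classify_rlu(spiked_rlus, cutoff) == "negative")
  tibble::tibble(
    analyte = analyte, cutoff_rule = rule_label, cutoff = cutoff,
    n_blank = length(blank_rlus), n_spiked = length(spiked_rlus),
    false_positive = fp, false_negative = fn,
    fp_rate = 100 * fp / length(blank_rlus),
    fn_rate = 100 * fn / length(spiked_rlus)
  )
}

#' Detection-capability (CCbeta) decision for one analyte
#'
#' Under the screening-validation design, a spike level at or below half the
#' regulatory limit is validated as the detection capability CCbeta when at
#' most `max_false_compliant` of the spiked controls screen negative under
#' the Fm cut-off; otherwise the spike level must be escalated and the
#' validation repeated with new data.
#'
#' @param error_counts One-row tibble from [count_errors()], computed under
#'   the `"Fm"` rule.
#' @param spec One analyte row (see [analyte_spec()] / [panel_analyte()]).
#' @param config A [validation_config()].
#' @return A one-row tibble with columns `analyte`, `spike_level`,
#'   `false_negative`, `decision` (`"validated"`/`"escalate"`), `cc_beta`
#'   (ug/kg, `NA` unless validated) and `below_mrl`.
#' @export
decide_ccbeta <- function(error_counts, spec, config = validation_config()) {
  if (nrow(error_counts) != 1)
    stop("decide_ccbeta: error_counts must be a single row")
  if (!identical(error_counts$cutoff_rule, "Fm"))
    stop("decide_ccbeta: error counts must be computed under the Fm rule")
  if (!is.na(error_counts$analyte) && error_counts$analyte != spec$name)
    stop(sprintf("decide_ccbeta: analyte mismatch (%s vs %s)",
                 error_counts$analyte, spec$name))
  validated <- error_counts$false_negative <= config$max_false_compliant
  cc_beta <- if (validated) spec$spike_level else NA_real_
  limit <- if (spec$prohibited) spec$screening_target else spec$mrl
  tibble::tibble(
    analyte = spec$name, spike_level = spec$spike_level,
    false_negative = error_counts$false_negative,
    decision = if (validated) "validated" else "escalate",
    cc_beta = cc_beta,
    below_mrl = if (validated) cc_beta <= limit else NA
  )
}

#' Validate a panel from blank and spiked control records
#'
#' For every panel analyte: computes the blank/spiked means and SDs, the
#' threshold T and the cut-off factor Fm, checks validity (`T > Fm`), counts
#' false positives/negatives under both cut-off choices, and takes the
#' CCbeta decision under the Fm rule. The chosen cut-off (used downstream by
#' [screen_samples()]) follows `cutoff_rule`, defaulting to Fm — the rule
#' that trades a slightly higher false-negative allowance for a near-zero
#' false-positive rate.
#'
#' @param records Sample-record tibble containing `analyte`, `rlu`, `cohort`
#'   with both a `"blank"` and a `"spiked"` cohort for every panel analyte
#'   (as produced by [simulate_validation_cohort()] or [read_samples()]).
#' @param panel A [panel_config()].
#' @param cutoff_rule `"Fm"` (default) or `"T"`.
#' @return An object of class `validation_report`: a list with tibbles
#'   `cutoffs` (per-analyte means/SDs, T, Fm, validity, chosen cut-off),
#'   `errors` (per-analyte counts under both rules), `ccbeta` (decisions),
#'   and a `summary` list (`all_valid`, `all_validated`,
#'   `analytes_below_mrl`, `cutoff_rule`).
#' @export
validate_panel <- function(records, panel, cutoff_rule = c("Fm", "T")) {
  stopifnot(inherits(panel, "panel_config"))
  cutoff_rule <- match.arg(cutoff_rule)
  cfg <- panel$validation
  cutoffs <- list(); errors <- list(); ccbeta <- list()
  for (i in seq_len(nrow(panel$analytes))) {
    s <- panel$analytes[i, ]
    blanks <- records$rlu[records$analyte == s$name & records$cohort == "blank"]
    spiked <- records$rlu[records$analyte == s$name & records$cohort == "spiked"]
    if (length(blanks) < 2 || length(spiked) < 2)
      stop(sprintf(paste0("validate_panel: analyte %s needs >= 2 blank and ",
                          ">= 2 spiked records (got %d blank, %d spiked)"),
                   s$name, length(blanks), length(spiked)))
    t_val <- threshold_t(blanks, cfg$t_factor)
    fm_val <- cutoff_fm(spiked, cfg$fm_factor)
    chosen <- if (cutoff_rule == "Fm") fm_val else t_val
    cutoffs[[i]] <- tibble::tibble(
      analyte = s$name,
      blank_mean = mean(blanks), blank_sd = stats::sd(blanks),
      spiked_mean = mean(spiked), spiked_sd = stats::sd(spiked),
      t_value = t_val, fm_value = fm_val, valid = t_val > fm_val,
      chosen_cutoff = chosen, cutoff_rule = cutoff_rule
    )
    err_t <- count_errors(blanks, spiked, t_val, "T", analyte = s$name)
    err_fm <- count_errors(blanks, spiked, fm_val, "Fm", analyte = s$name)
    errors[[i]] <- dplyr::bind_rows(err_t, err_fm)
    ccbeta[[i]] <- decide_ccbeta(err_fm, s, cfg)
  }
  cutoffs <- dplyr::bind_rows(cutoffs)
  ccbeta <- dplyr::bind_rows(ccbeta)
  structure(list(
    cutoffs = cutoffs,
    errors = dplyr::bind_rows(errors),
    ccbeta = ccbeta,
    summary = list(
      all_valid = all(cutoffs$valid),
      all_validated = all(ccbeta$decision == "validated"),
      analytes_below_mrl = sum(ccbeta$below_mrl, na.rm = TRUE),
      cutoff_rule = cutoff_rule
    )
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d analytes, cut-off rule %s\n",
              nrow(x$cutoffs), x$summary$cutoff_rule))
  cat(sprintf("  T > Fm for all analytes: %s; all spike levels validated: %s; %d below MRL\n",
              x$summary$all_valid, x$summary$all_validated,
              x$summary$analytes_below_mrl))
  tab <- dplyr::left_join(
    x$cutoffs[, c("analyte", "t_value", "fm_value", "valid", "chosen_cutoff")],
    x$ccbeta[, c("analyte", "spike_level", "false_negative", "decision", "cc_beta")],
    by = "analyte"
  )
  print(tab, n = nrow(tab))
  invisible(x)
}
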