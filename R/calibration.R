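# Competitive four-parameter-logistic calibration curves: RLU as a strictly
# decreasing function of on-chip concentration, and the closed-form inverse
# used for concentration back-calculation.

#' Construct a competitive 4-parameter-logistic calibration model
#'
#' Signal model `rlu(c) = bottom + (top - bottom) / (1 + (c / c50)^slope)`:
#' `top` is the zero-concentration (full conjugate binding) signal, `bottom`
#' the saturating-concentration floor, `c50` the concentration giving the
#' half-maximal signal and `slope` the Hill coefficient. The concentration
#' axis is the on-chip (diluted) concentration in ug/kg; sample
#' concentrations are recovered by multiplying the inverse by the dilution
#' factor (see [screen_samples()]).
#'
#' @param analyte Analyte code the curve belongs to.
#' @param top RLU at zero concentration; must exceed `bottom`.
#' @param bottom RLU at saturating concentration; non-negative.
#' @param c50 Concentration (ug/kg) at the curve midpoint; positive.
#' @param slope Hill coefficient; positive.
#' @return An object of class `calibration_model`.
#' @export
#' @examples
#' m <- calibration_model("SDZ", top = 5000, bottom = 200, c50 = 10, slope = 1)
#' signal_at(c(0, 10, 30), m)
calibration_model <- function(analyte, top, bottom, c50, slope) {
  if (!is.finite(top) || !is.finite(bottom) || bottom < 0 || top <= bottom)
    stop("calibration_model: need top > bottom >= 0 (competitive format)")
  if (!is.finite(c50) || c50 <= 0) stop("calibration_model: c50 must be > 0")
  if (!is.finite(slope) || slope <= 0) stop("calibration_model: slope must be > 0")
  structure(list(analyte = as.character(analyte), top = as.numeric(top),
                 bottom = as.numeric(bottom), c50 = as.numeric(c50),
                 slope = as.numeric(slope)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model %s> top=%g bottom=%g c50=%g slope=%g\n",
              x$analyte, x$top, x$bottom, x$c50, x$slope))
  invisible(x)
}

#' Expected RLU at a concentration
#'
#' Evaluates the competitive logistic; strictly decreasing in `conc`, equal
#' to `top` at zero concentration.
#'
#' @param conc Concentration(s) in ug/kg, non-negative.
#' @param model A [calibration_model()].
#' @return Numeric vector of expected RLU.
#' @export
signal_at <- function(conc, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("signal_at: conc must be finite and >= 0")
  model$bottom + (model$top - model$bottom) /
    (1 + (conc / model$c50)^model$slope)
}

#' Back-calculate concentration from RLU
#'
#' Closed-form inverse of [signal_at()]. Signals at or above `top` are below
#' the detectable range (returned concentration 0, flag
#' `"below_detection"`); signals at or below `bottom` are saturated (the
#' concentration exceeds the calibration range and is censored as `NA`, flag
#' `"above_range"`). Interior signals return the exact inverse with flag
#' `"ok"`; across the working range of the curve (within about two decades
#' of `c50`) the round trip through [signal_at()] is accurate to 1e-9
#' relative error, degrading only in the extreme tails where the signal is
#' numerically indistinguishable from `top` or `bottom`.
#'
#' @param rlu Signal value(s) in RLU.
#' @param model A [calibration_model()].
#' @return A tibble with columns `conc` (ug/kg, on-chip scale) and `flag`
#'   (one of `"ok"`, `"below_detection"`, `"above_range"`), one row per
#'   input signal.
#' @export
#' @examples
#' m <- calibration_model("SDZ", 5000, 200, 10, 1)
#' inverse_signal(signal_at(17.3, m), m)
inverse_signal <- function(rlu, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(rlu))) stop("inverse_signal: rlu must be finite")
  conc <- rep(NA_real_, length(rlu))
  flag <- rep("ok", length(rlu))
  lo <- rlu <= model$bottom
  hi <- rlu >= model$top
  ok <- !lo & !hi
  conc[hi] <- 0
  flag[hi] <- "below_detection"
  flag[lo] <- "above_range"   # censored: concentration above calib_max
  conc[ok] <- model$c50 *
    ((model$top - rlu[ok]) / (rlu[ok] - model$bottom))^(1 / model$slope)
  tibble::tibble(conc = conc, flag = flag)
}

#' Default calibration models for a panel
#'
#' Illustrative per-analyte curves for the synthetic-data generator. The
#' zero-concentration signals (`top`) are set to the magnitude of the real
#' assay's blank signals per analyte for realism; they are illustrative, not
#' fitted (the instrument's internal calibrators are not published). Each
#' curve places its midpoint at one quarter of the on-chip spike
#' concentration (`c50 = spike_level / (4 * dilution_factor)`), so spiked
#' controls read far down the curve, well separated from blanks.
#'
#' @param panel A [panel_config()].
#' @return A named list of [calibration_model()] objects, one per panel
#'   analyte.
#' @export
default_models <- function(panel = default_panel()) {
  stopifnot(inherits(panel, "panel_config"))
  tops <- c(SDZ = 4900, SDIM = 3400, SQX = 7650, SMTZ = 3050, SMXZ = 3100,
            STZ = 7150, SSX = 3650, SPD = 2700, SMZ = 6400, SMMX = 1950,
            SMPD = 3500, SCPD = 7650, DAP = 4800, SDX = 2800, TMPM = 1500)
  d <- panel$validation$dilution_factor
  models <- lapply(seq_len(nrow(panel$analytes)), function(i) {
    s <- panel$analytes[i, ]
    top <- if (s$name %in% names(tops)) tops[[s$name]] else 4000
    calibration_model(
      analyte = s$name, top = top, bottom = round(0.04 * top),
      c50 = s$spike_level / (4 * d), slope = 1.3
    )
  })
  names(models) <- panel$analytes$name
  models
}
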