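# Seeded synthetic RLU data: blank/spiked validation cohorts and survey
# cohorts with configurable contamination, built on the competitive
# calibration curves.

#' Construct a measurement-noise model
#'
#' Signal noise is a bounded multiplicative loss factor times the expected
#' signal, plus additive read-out noise, clipped at zero:
#' `rlu = E[rlu] * shift * M + N(0, floor_sd)`, `M = 1 + cv * Z` where `Z`
#' is a standardized Beta(8, 1) variate (mean 0, SD 1). `M` has mean 1 and
#' coefficient of variation `cv`, is left-skewed and bounded above at about
#' `1 + 1.07 * cv`: the chemiluminescent signal cannot exceed the
#' full-binding ceiling by much, while losses (incomplete binding, washing)
#' tail downward. `floor_sd` is symmetric additive camera/read-out noise in
#' RLU. `matrix_shift` applies a per-milk-type multiplicative factor
#' (defaults 1: fat content does not shift the assay).
#'
#' @param cv Coefficient of variation of the multiplicative signal noise.
#' @param floor_sd SD of the additive RLU noise.
#' @param matrix_shift Named numeric factors for milk types `skimmed`,
#'   `semi`, `full_fat`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.08, floor_sd = 5,
                        matrix_shift = c(skimmed = 1, semi = 1, full_fat = 1)) {
  if (!is.finite(cv) || cv < 0) stop("noise_model: cv must be >= 0")
  if (!is.finite(floor_sd) || floor_sd < 0) stop("noise_model: floor_sd must be >= 0")
  ms <- c(skimmed = 1, semi = 1, full_fat = 1)
  ms[names(matrix_shift)] <- as.numeric(matrix_shift)
  if (any(!is.finite(ms)) || any(ms <= 0))
    stop("noise_model: matrix_shift factors must be > 0")
  structure(list(cv = as.numeric(cv), floor_sd = as.numeric(floor_sd),
                 matrix_shift = ms),
            class = "noise_model")
}

# Beta(8, 1) standardized to mean 0, SD 1: loss-shaped multiplicative noise.
.noise_shape <- c(a = 8, b = 1)

rnoise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  a <- .noise_shape[["a"]]; b <- .noise_shape[["b"]]
  mu <- a / (a + b)
  sdev <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  1 + cv * (stats::rbeta(n, a, b) - mu) / sdev
}

measure_rlu <- function(true_conc, model, noise, milk_type, dilution_factor) {
  expected <- signal_at(true_conc / dilution_factor, model)
  shift <- noise$matrix_shift[milk_type]
  raw <- expected * shift * rnoise_factor(length(true_conc), noise$cv) +
    stats::rnorm(length(true_conc), 0, noise$floor_sd)
  pmax(raw, 0)
}

#' Generate a blank + spiked validation cohort
#'
#' For every panel analyte, emits `n_blank` analyte-free records
#' (`true_conc = 0`) and `n_spiked` records fortified at the analyte's spike
#' level, measured through its calibration curve at the on-chip
#' concentration `true_conc / dilution_factor` with the given noise model.
#' Identical arguments and seed give identical output.
#'
#' @param panel A [panel_config()].
#' @param models Named list of [calibration_model()]s covering every panel
#'   analyte.
#' @param noise A [noise_model()].
#' @param seed Integer seed; all randomness derives from it.
#' @param milk_type Milk type label assigned to the control samples.
#' @return A tibble of sample records with columns `sample_id`, `analyte`,
#'   `rlu`, `cohort` (`"blank"`/`"spiked"`), `true_conc`, `milk_type`,
#'   `seed_meta`.
#' @export
#' @examples
#' v <- simulate_validation_cohort(default_panel(), seed = 1)
#' nrow(v)  # 15 analytes x (20 blank + 20 spiked)
simulate_validation_cohort <- function(panel, models = default_models(panel),
                                       noise = noise_model(), seed = 1,
                                       milk_type = "skimmed") {
  stopifnot(inherits(panel, "panel_config"), inherits(noise, "noise_model"))
  missing <- setdiff(panel$analytes$name, names(models))
  if (length(missing))
    stop("simulate_validation_cohort: no calibration model for: ",
         paste(missing, collapse = ", "))
  milk_type <- match.arg(milk_type, names(noise$matrix_shift))
  cfg <- panel$validation
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(panel$analytes)), function(i) {
      s <- panel$analytes[i, ]
      m <- models[[s$name]]
      conc <- c(rep(0, cfg$n_blank), rep(s$spike_level, cfg$n_spiked))
      cohort <- rep(c("blank", "spiked"), c(cfg$n_blank, cfg$n_spiked))
      tibble::tibble(
        sample_id = sprintf("%s-%s-%02d", tolower(cohort), s$name,
                            c(seq_len(cfg$n_blank), seq_len(cfg$n_spiked))),
        analyte = s$name,
        rlu = measure_rlu(conc, m, noise, milk_type, cfg$dilution_factor),
        cohort = cohort,
        true_conc = conc,
        milk_type = milk_type,
        seed_meta = sprintf("validation seed=%d", seed)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Generate a survey cohort with configurable contamination
#'
#' Emits `n_samples` milk samples, each measured for every panel analyte.
#' Sample `j` is contaminated with analyte `a` with probability
#' `prevalence[a]`, drawing its true concentration from
#' `conc_distribution[[a]]` (default: fixed at the analyte's spike level);
#' otherwise the true concentration is 0. Milk types are drawn from
#' `milk_mix`. `spike_in` deterministically overrides chosen cells after the
#' random draw, e.g. to force exactly one contaminated sample.
#'
#' @param panel A [panel_config()].
#' @param models Named list of [calibration_model()]s.
#' @param noise A [noise_model()].
#' @param n_samples Number of survey samples.
#' @param prevalence Per-analyte contamination probability: a single number
#'   recycled to all analytes, or a named vector (unnamed analytes get 0).
#' @param conc_distribution Optional named list of functions `f(n)` drawing
#'   `n` contaminated concentrations for an analyte; default draws at the
#'   spike level.
#' @param milk_mix Named proportions over `skimmed`, `semi`, `full_fat`;
#'   must sum to 1. Default matches a 15/17/21 split of 53 retail samples.
#' @param seed Integer seed.
#' @param spike_in Optional `data.frame(sample, analyte, conc)` forcing
#'   sample number `sample` to carry `conc` ug/kg of `analyte` (RLU redrawn
#'   under the same seed stream).
#' @return A tibble of survey sample records (columns as in
#'   [simulate_validation_cohort()], `cohort = "survey"`).
#' @export
simulate_survey_cohort <- function(panel, models = default_models(panel),
                                   noise = noise_model(), n_samples = 53,
                                   prevalence = 0, conc_distribution = NULL,
                                   milk_mix = c(skimmed = 15 / 53,
                                                semi = 17 / 53,
                                                full_fat = 21 / 53),
                                   seed = 1, spike_in = NULL) {
  stopifnot(inherits(panel, "panel_config"), inherits(noise, "noise_model"))
  analytes <- panel$analytes$name
  missing <- setdiff(analytes, names(models))
  if (length(missing))
    stop("simulate_survey_cohort: no calibration model for: ",
         paste(missing, collapse = ", "))
  if (is.null(names(prevalence))) {
    if (length(prevalence) != 1)
      stop("simulate_survey_cohort: unnamed prevalence must be a single number")
    prev <- stats::setNames(rep(prevalence, length(analytes)), analytes)
  } else {
    prev <- stats::setNames(rep(0, length(analytes)), analytes)
    unknown <- setdiff(names(prevalence), analytes)
    if (length(unknown))
      stop("simulate_survey_cohort: prevalence for unknown analyte: ",
           paste(unknown, collapse = ", "))
    prev[names(prevalence)] <- prevalence
  }
  if (any(prev < 0 | prev > 1))
    stop("simulate_survey_cohort: prevalence must lie in [0, 1]")
  if (abs(sum(milk_mix) - 1) > 1e-8 || any(milk_mix < 0))
    stop("simulate_survey_cohort: milk_mix must be non-negative and sum to 1")
  types <- names(noise$matrix_shift)
  if (!all(names(milk_mix) %in% types))
    stop("simulate_survey_cohort: milk_mix names must be among: ",
         paste(types, collapse = ", "))
  cfg <- panel$validation

  withr::with_seed(seed, {
    milk <- sample(names(milk_mix), n_samples, replace = TRUE, prob = milk_mix)
    recs <- lapply(seq_len(n_samples), function(j) {
      contaminated <- stats::runif(length(analytes)) < prev
      conc <- vapply(seq_along(analytes), function(k) {
        if (!contaminated[k]) return(0)
        a <- analytes[k]
        f <- conc_distribution[[a]]
        if (is.null(f)) panel$analytes$spike_level[k] else f(1)
      }, numeric(1))
      tibble::tibble(
        sample_id = sprintf("survey-%03d", j),
        analyte = analytes,
        true_conc = conc,
        milk_type = milk[j]
      )
    })
    recs <- dplyr::bind_rows(recs)
    if (!is.null(spike_in)) {
      for (i in seq_len(nrow(spike_in))) {
        row <- which(recs$sample_id == sprintf("survey-%03d", spike_in$sample[i]) &
                       recs$analyte == spike_in$analyte[i])
        if (!length(row))
          stop("simulate_survey_cohort: spike_in refers to unknown sample/analyte")
        recs$true_conc[row] <- spike_in$conc[i]
      }
    }
    recs$rlu <- NA_real_
    for (a in analytes) {
      idx <- which(recs$analyte == a)
      recs$rlu[idx] <- measure_rlu(recs$true_conc[idx], models[[a]], noise,
                                   recs$milk_type[idx], cfg$dilution_factor)
    }
    tibble::tibble(
      sample_id = recs$sample_id, analyte = recs$analyte, rlu = recs$rlu,
      cohort = "survey", true_conc = recs$true_conc,
      milk_type = recs$milk_type,
      seed_meta = sprintf("survey seed=%d", seed)
    )
  })
}
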