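---
title: "Screening validation for a multiplex biochip milk panel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening validation for a multiplex biochip milk panel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkscreen)
```

## The screening-validation model

A competitive chemiluminescent biochip immunoassay reports, for each
analyte, a signal in relative light units (RLU) that decreases with the
analyte concentration: analyte in the sample competes with an
enzyme-labelled conjugate for antibody binding, so blanks read high and
contaminated samples read low.

The EU framework for validating screening methods asks for a cut-off
level that separates "screen negative" from "screen positive", and for a
demonstration that at the screening target concentration the method's
false-compliant (false-negative) rate β is at most 5%. With a screening
target at or below half the regulatory limit, analysing 20 spiked
controls and observing at most one false compliant suffices to declare
the detection capability CCβ equal to the spike level.

`milkscreen` implements this per analyte from two control cohorts:

* **Threshold** from the `n_blank = 20` blank controls:
  `T = mean(blank RLU) − t_factor · SD(blank RLU)`, `t_factor = 1.6`.
* **Cut-off factor** from the `n_spiked = 20` spiked controls:
  `Fm = mean(spiked RLU) + fm_factor · SD(spiked RLU)`,
  `fm_factor = 1.64`, the one-sided 5% normal quantile.
* **Validity**: the validation is usable only when `T > Fm`. Otherwise
  the spike level is too close to the blank distribution and must be
  escalated; `milkscreen` reports the `escalate` decision but never
  auto-runs it, because escalation requires new data at a higher spike
  level.
* **Classification**: a sample screens positive iff its RLU is *strictly
  below* the cut-off. Equality screens negative: the source rule is
  "lower than", and although ties have probability zero for continuous
  signals, the tie-break must be deterministic.
* **Error accounting**: false positives are blanks screening positive,
  false negatives are spiked controls screening negative, reported as
  counts and percentages of their cohort sizes under *both* cut-off
  choices (T and Fm). Choosing T as the cut-off gives more sensitivity
  and more false positives; choosing Fm gives near-zero false positives
  at a bounded false-negative allowance. The runtime default is Fm.
* **CCβ decision** (always under the Fm rule): validated with
  `CCβ = spike_level` when `FN ≤ max_false_compliant = 1`, else
  escalate. `below_mrl` compares CCβ to the analyte MRL, or to the
  screening target for prohibited substances.

Assumptions worth making explicit: the per-analyte error model of the
guideline is used as printed — no multiplicity adjustment is applied
across the 15 analytes, since the regulatory decision is per analyte;
and the SD is the sample SD with the n−1 denominator (the guideline does
not specify; n−1 is the standard small-n choice, and both multipliers
are configurable via `validation_config()`).

## The default panel

`default_panel()` ships the 15-analyte milk panel: 13 sulphonamides
(group MRL 100 µg/kg on the *sum* of residues), trimethoprim (MRL
50 µg/kg, spike 10 µg/kg) and dapsone. Spike levels are at or below half
the relevant limit (20 µg/kg for most sulphonamides, 12 µg/kg for
sulphamethoxazole, 50 µg/kg for sulphamonomethoxine whose calibration
range extends to 240 µg/kg). Calibration ranges are stored exactly as
supplied with the assay — they already account for the 1:1 wash-buffer
dilution (factor 2) — so the dilution factor is applied only once, when
back-calculating concentrations.

Dapsone is prohibited and has no MRL; the guideline only asks that
screening reach "the relevant regulatory concentration", which it does
not quantify for milk. We give DAP a `screening_target` equal to its
20 µg/kg spike level so every analyte flows through the same decision
code; compliance for DAP simply means screening negative. This is a
package convention, not a regulatory fact.

The threshold multiplier is stored as 1.6 and the cut-off multiplier as
1.64. Printed sources sometimes typeset these decimals ambiguously; the
magnitudes of published T/Fm tables and the guideline's one-sided 5%
factor are consistent only with 1.6/1.64, and both are configurable if a
laboratory's SOP differs.

## The synthetic-data generator

No raw RLU data are published for assays of this type, so the package
generates them. The generator defines the study conditions the tests
run under; its defaults are fixed and documented here.

**Calibration curves.** Each analyte gets a four-parameter logistic
`rlu(c) = bottom + (top − bottom) / (1 + (c/c50)^slope)` on the on-chip
(diluted) concentration axis. The 4PL is the conventional form for
competitive immunoassay calibration; the assay itself only fixes the
direction of the effect. Default `top` values (≈1500–7650 RLU per
analyte) are set to the magnitude of real blank signals for realism and
are illustrative, not fitted; `bottom = 0.04·top`,
`c50 = spike_level/(4·dilution_factor)` and `slope = 1.3`, which places
a spiked control at roughly 18% of its curve's dynamic range — far below
the blanks, as the competitive format requires.

**Measurement and dilution.** A sample with true concentration `c` is
measured at `signal_at(c / dilution_factor)`: the 1:1 dilution happens
physically before measurement, and `screen_samples()` multiplies
back-calculated concentrations by the same factor. Keeping the dilution
on one side only makes end-to-end concentration recovery exact in the
zero-noise limit (a test asserts this). Validation statistics live
entirely in RLU and are unaffected. The spiking procedure itself is
absorbed into `true_conc = spike_level`: working solutions are defined
to land on the nominal level.

**Noise.** Observed RLU is
`expected · matrix_shift · M + N(0, floor_sd)`, clipped at zero, with
`M = 1 + cv·Z` and `Z` a standardized Beta(8, 1) variate (mean 0,
SD 1). `M` therefore has mean 1 and coefficient of variation `cv`
(default 0.08, a typical immunoassay imprecision; no published variance
data exist to fit), and `floor_sd` (default 5 RLU) is additive camera
read-out noise. The Beta shape is deliberate: it is left-skewed and
bounded above at about `1 + 1.07·cv`. Physically, the chemiluminescent
signal cannot exceed the full-binding ceiling by much — the error budget
is dominated by *losses* (incomplete binding, washing, quenching) which
tail downward. Statistically, this shape is what makes the validation
design behave the way published validations of this assay class do: the
in-sample false-negative count against `Fm = mean + 1.64·SD` of the
same 20 spiked controls is almost surely 0 or 1, and the in-sample
false-positive count under the T rule ranges over 0–3. A symmetric or
right-skewed noise (e.g. lognormal) instead yields two or more
false negatives for at least one of 15 analytes in most runs, making
"every analyte validated" — routinely reported for real panels —
practically unreachable in simulation. `matrix_shift` (per milk type,
default 1 for skimmed, semi-skimmed and full-fat) exists because the
generator models milk-type structure, but defaults to no effect: fat
content does not shift this assay.

**Cohorts.** `simulate_validation_cohort()` emits 20 blank + 20 spiked
records per analyte (600 rows for the default panel);
`simulate_survey_cohort()` emits `n_samples` samples (default 53,
milk-type mix 15/17/21 skimmed/semi/full-fat, matching a typical retail
survey) measured for all 15 analytes, contaminated per analyte with
probability `prevalence` at concentrations drawn from
`conc_distribution` (default: the spike level). `spike_in` overrides
chosen cells deterministically, e.g. to force exactly one contaminated
sample. All generators are driven by an explicit `seed` through an
isolated RNG scope: equal arguments give bit-identical output and the
caller's RNG state is untouched.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: inter-assay drift and reagent-lot
effects, cross-reactivity between structurally related sulphonamides,
spatial effects on the biochip, heteroscedasticity beyond the CV model,
and genuinely unknown real-data dispersion (the `cv = 0.08` default is a
declared assumption, not an estimate). Conclusions about a real assay
require its own validation data in the same tabular format.

## Numerical choices and degenerate inputs

* `threshold_t()`/`cutoff_fm()` require ≥ 2 values (SD undefined
  otherwise) and match an independent two-pass mean/SD computation to
  1e-9 relative error.
* `inverse_signal()` is the closed-form 4PL inverse; the round trip
  through `signal_at()` is accurate to 1e-9 relative error across the
  working range (within about two decades of `c50`). Signals at or above
  `top` return concentration 0 flagged `below_detection`; signals at or
  below `bottom` are censored (`NA`, flag `above_range`) rather than
  given a fabricated number beyond the calibration range.
* Zero noise (`cv = 0, floor_sd = 0`) collapses blank cohorts to exactly
  `top · matrix_shift`; zero-variance cohorts give `T = Fm = mean`.
* Survey percentages are stored exactly (`100·n_positive/n_samples`);
  the text rendering truncates to two decimals (1 of 53 prints as
  1.88%), the convention of published occurrence tables.
* "Compliant" is a screening-level property: negative for every analyte.
  The summed-sulphonamide comparison against the 100 µg/kg group MRL is
  a separate, concentration-level check, available only when calibration
  models are supplied; the two are reported side by side, never
  conflated.

## Known limitations

A single n = 20 validation carries sampling slack: the Fm of one run
occasionally underestimates the spiked-signal spread, and the
*out-of-sample* sensitivity at the spike level for that analyte can then
dip below the design's 95% even though the in-sample check passed. This
is a property of any small-n cut-off validation, not of the
implementation; the test suite therefore estimates sensitivity at the
design level, pooling 10 independent validation runs × 100 contaminated
samples per analyte (1000 total), and checks ≥ 95% per analyte. The
escalation loop, confirmatory decision limits (CCα) and calibration-curve
fitting from raw calibrator data are out of scope.

## Problem sizes

The test suite and the reproduction script run the study-sized designs
directly: 20 + 20 controls per analyte, 53-sample surveys, 30-seed
validity sweeps, 1000-sample sensitivity estimates and the 100,000-draw
calibration check of the Fm rule (whose long-run false-negative rate
under a normal spiked-signal model is P(Z > 1.64) ≈ 5.05%, the 5% the
design targets).
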