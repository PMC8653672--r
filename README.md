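# milkscreen

Validation and screening statistics for multiplex biochip immunoassay
panels that screen veterinary antibiotic residues in milk.

## The problem

Competitive chemiluminescent biochip arrays measure many antibiotic
residues from a single milk sample at once: each test region reports a
signal in relative light units (RLU) that *decreases* as the analyte
concentration rises, because sample analyte competes with enzyme-labelled
conjugate for antibody binding. Before such an assay may be used for
regulatory screening, the EU framework (Commission Decision 2002/657/EC
and the CRL guideline for validating screening methods) requires a
cut-off level and a demonstration of the detection capability CCβ — the
lowest concentration at which the method flags the analyte with a
false-compliant (β) error of at most 5%.

`milkscreen` implements that workflow for a 15-analyte milk panel
(13 sulphonamides with a 100 µg/kg group MRL on their sum, trimethoprim
with a 50 µg/kg MRL, and dapsone, a prohibited substance):

- **Threshold** `T = mean(blank RLU) − 1.6 · SD(blank RLU)` from 20 blank
  controls;
- **Cut-off factor** `Fm = mean(spiked RLU) + 1.64 · SD(spiked RLU)` from
  20 controls spiked at the screening target (≤ ½ MRL);
- the validation is usable only when `T > Fm`;
- a sample **screens positive** when its RLU lies strictly below the
  chosen cut-off (Fm by default);
- the spike level is **validated as CCβ** when at most one of the twenty
  spiked controls screens negative; otherwise the spike level must be
  escalated and the validation repeated;
- survey cohorts are screened against the per-analyte cut-offs, with
  optional concentration back-calculation through the four-parameter
  logistic calibration curve (times the sample dilution factor 2) and an
  MRL-compliance summary including the summed-sulphonamide check.

Because raw instrument RLU data are rarely published, the package also
ships a seeded synthetic-data generator: per-analyte competitive 4PL
calibration models, a bounded left-skewed multiplicative noise model, and
blank/spiked validation cohorts plus survey cohorts with configurable
contamination. It is intended for residue-lab analysts and method
developers who want to rehearse, audit, or teach the validation
arithmetic, and to process real per-analyte RLU tables in the same
format.

## Worked example

```r
library(milkscreen)

panel   <- default_panel()                              # the 15-analyte kit panel
records <- simulate_validation_cohort(panel, seed = 1)  # 20 blank + 20 spiked per analyte
report  <- validate_panel(records, panel)               # T, Fm, errors, CCbeta
report
#> <validation_report> 15 analytes, cut-off rule Fm
#>   T > Fm for all analytes: TRUE; all spike levels validated: TRUE; 15 below MRL
#>    analyte t_value fm_value valid chosen_cutoff spike_level false_negative
#>  1 SDZ       4397.     946. TRUE           946.          20              0
#>  2 SDIM      2995.     637. TRUE           637.          20              1
#>  3 SQX       6472.    1527. TRUE          1527.          20              0
#>  ...
#> 15 TMPM      1293.     304. TRUE           304.          10              0
```

Every analyte's threshold `T` exceeds its cut-off `Fm`, so the validation
is usable; no analyte shows more than one false negative of its twenty
spiked controls, so each spike level is validated as CCβ (e.g. 10 µg/kg
for trimethoprim — well below its 50 µg/kg MRL).

Screening a 53-sample survey cohort in which exactly one sample carries
sulphamethazine at 20 µg/kg:

```r
survey <- simulate_survey_cohort(panel, n_samples = 53, prevalence = 0, seed = 2,
                                 spike_in = data.frame(sample = 30,
                                                       analyte = "SMTZ", conc = 20))
calls  <- screen_samples(survey, report, models = default_models(panel),
                         dilution_factor = 2)
survey_summary(calls, panel)
#> <survey_report> 53 samples, 52 compliant (98.11%)
#>    analyte cutoff n_positive pct_positive
#>  1 SDZ       946.          0         0
#>  4 SMTZ      630.          1         1.89
#>  ...
```

The contaminated sample is the only screen positive (1 of 53, printed as
1.88% under the truncated two-decimal table convention); all other
samples are compliant.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/milkscreen.R simulate --cohort validation --seed 1 --output validation.csv
Rscript inst/cli/milkscreen.R validate --samples validation.csv --output report.json --table report.txt
Rscript inst/cli/milkscreen.R simulate --cohort survey --seed 2 --output survey.csv
Rscript inst/cli/milkscreen.R screen   --samples survey.csv --report report.json --output survey.json
```

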