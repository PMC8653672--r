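Package: milkscreen
Title: Validation and Screening Statistics for Multiplex Biochip
    Antibiotic-Residue Immunoassays in Milk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating competitive chemiluminescent immunoassay
    screening methods for veterinary antibiotic residues in milk, following
    the EU screening-validation framework (Commission Decision 2002/657/EC
    and the CRL screening guideline). Implements the blank-derived threshold
    T = mean - 1.6*SD, the spiked-derived cut-off factor Fm = mean + 1.64*SD,
    the T > Fm validity check, false-positive/false-negative accounting under
    either cut-off choice, and the detection-capability (CCbeta) decision
    rule (at most one false compliant of twenty spiked controls). Ships the
    15-analyte sulphonamide/dapsone/trimethoprim milk panel with its MRLs,
    spike levels and calibration ranges as the default configuration, a
    seeded synthetic-data generator for blank/spiked validation cohorts and
    contaminated survey cohorts built on a four-parameter-logistic
    competitive calibration model, and survey screening with MRL-compliance
    summaries. A command-line wrapper ties simulation, validation and
    screening into one reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
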