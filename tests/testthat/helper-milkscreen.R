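# Shared helpers: independent oracles and random-case generators.

# Two-pass mean/SD oracle built on elementary sums only, independent of
# stats::sd / threshold_t / cutoff_fm.
oracle_mean <- function(x) sum(x) / length(x)
oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Draw a random valid competitive calibration model.
random_model <- function(analyte = "X") {
  top <- runif(1, 1000, 9000)
  bottom <- runif(1, 0, 0.2 * top)
  calibration_model(analyte, top = top, bottom = bottom,
                    c50 = runif(1, 0.5, 30), slope = runif(1, 0.6, 3))
}

# Naive per-record loop classifier/counter (oracle for count_errors).
naive_counts <- function(blanks, spiked, cutoff) {
  fp <- 0L
  for (b in blanks) if (b < cutoff) fp <- fp + 1L
  fn <- 0L
  for (s in spiked) if (s >= cutoff) fn <- fn + 1L
  c(fp = fp, fn = fn)
}
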