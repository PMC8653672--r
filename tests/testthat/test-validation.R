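test_that("threshold T and cut-off Fm match hand-computed values", {
  # hand oracle: mean 4000, sample SD sqrt(80000/3) = 163.2993...
  expect_equal(threshold_t(c(4000, 4200, 3800, 4000), 1.6), 3738.7211,
               tolerance = 1e-4)
  # hand oracle: mean 300, sample SD sqrt(5000/3) = 40.8248...
  expect_equal(cutoff_fm(c(300, 350, 250, 300), 1.64), 366.9527,
               tolerance = 1e-4)
  # zero-variance degeneracy
  expect_equal(threshold_t(rep(3000, 5)), 3000)
  expect_equal(cutoff_fm(rep(400, 5)), 400)
  expect_error(threshold_t(4000), "at least 2")
  expect_error(cutoff_fm(numeric(0)), "at least 2")
})

test_that("T and Fm agree with an independent two-pass oracle on random inputs", {
  withr::with_seed(21, {
    for (i in 1:50) {
      x <- runif(sample(2:200, 1), 0, 10000)
      tf <- runif(1, 0.1, 3)
      expect_equal(threshold_t(x, tf), oracle_mean(x) - tf * oracle_sd(x),
                   tolerance = 1e-9)
      expect_equal(cutoff_fm(x, tf), oracle_mean(x) + tf * oracle_sd(x),
                   tolerance = 1e-9)
      # Fm never falls below the spiked mean
      expect_gte(cutoff_fm(x, 1.64), oracle_mean(x))
    }
  })
})

test_that("reported assay cut-offs satisfy the validity check and positivity rule", {
  # the validated assay reported T = 4282.65 and Fm = 406.78 RLU for SDZ
  expect_true(4282.65 > 406.78)
  expect_equal(classify_rlu(100, 406.78), "positive")
  expect_equal(classify_rlu(406.78, 406.78), "negative")  # boundary convention
  expect_equal(classify_rlu(10000, 406.78), "negative")
})

test_that("count_errors equals a naive per-record loop and worked examples", {
  # 20 spiked with exactly one at/above the cut-off: FN 1, rate 5%
  spiked <- c(rep(300, 19), 500)
  e <- count_errors(rep(4000, 20), spiked, cutoff = 450, "Fm")
  expect_equal(e$false_negative, 1L)
  expect_equal(e$fn_rate, 5)
  expect_equal(e$false_positive, 0L)

  # 20 blanks of which 3 below T: FP 3, rate 15%
  blanks <- c(rep(4000, 17), 100, 150, 200)
  e2 <- count_errors(blanks, rep(300, 20), cutoff = 3000, "T")
  expect_equal(e2$false_positive, 3L)
  expect_equal(e2$fp_rate, 15)

  # cut-off below everything: no FP, all spiked negative
  e3 <- count_errors(blanks, spiked, cutoff = 0, "Fm")
  expect_equal(e3$false_positive, 0L)
  expect_equal(e3$false_negative, 20L)

  withr::with_seed(22, {
    for (i in 1:30) {
      b <- runif(sample(2:40, 1), 0, 5000)
      s <- runif(sample(2:40, 1), 0, 5000)
      cut <- runif(1, 0, 5000)
      e <- count_errors(b, s, cut, "Fm")
      nv <- naive_counts(b, s, cut)
      expect_equal(e$false_positive, unname(nv["fp"]))
      expect_equal(e$false_negative, unname(nv["fn"]))
    }
  })
})

test_that("raising the cut-off weakly increases FP and weakly decreases FN", {
  withr::with_seed(23, {
    for (i in 1:20) {
      b <- rnorm(20, 4000, 400)
      s <- rnorm(20, 400, 60)
      cuts <- sort(runif(15, 0, 5000))
      fp <- fn <- numeric(length(cuts))
      for (k in seq_along(cuts)) {
        e <- count_errors(b, s, cuts[k], "Fm")
        fp[k] <- e$false_positive
        fn[k] <- e$false_negative
      }
      expect_true(all(diff(fp) >= 0))
      expect_true(all(diff(fn) <= 0))
    }
  })
})

test_that("the Fm rule is calibrated to ~5% false negatives under a normal model", {
  withr::with_seed(24, {
    calib <- rnorm(1e5, 400, 50)
    fm <- cutoff_fm(calib, 1.64)
    fresh <- rnorm(1e5, 400, 50)
    fn_rate <- 100 * mean(classify_rlu(fresh, fm) == "negative")
  })
  # long-run false-negative rate P(Z > 1.64) = 5.05%, within Monte-Carlo error
  expect_lt(abs(fn_rate - 100 * pnorm(1.64, lower.tail = FALSE)), 0.3)
})

test_that("separated cohorts are algebraically guaranteed valid", {
  # if mean(b) - mean(s) > t_factor*sd(b) + fm_factor*sd(s), then T > Fm
  withr::with_seed(25, {
    checked <- 0
    for (i in 1:50) {
      b <- rnorm(20, runif(1, 3000, 8000), runif(1, 100, 800))
      s <- rnorm(20, runif(1, 200, 900), runif(1, 20, 200))
      if (mean(b) - mean(s) > 1.6 * oracle_sd(b) + 1.64 * oracle_sd(s)) {
        expect_true(threshold_t(b, 1.6) > cutoff_fm(s, 1.64))
        checked <- checked + 1
      }
    }
    expect_gt(checked, 10)  # the property was actually exercised
  })
})

test_that("CCbeta decision follows the one-false-compliant rule", {
  p <- default_panel()
  cfg <- p$validation
  err <- function(analyte, fn) tibble::tibble(
    analyte = analyte, cutoff_rule = "Fm", cutoff = 300, n_blank = 20L,
    n_spiked = 20L, false_positive = 0L, false_negative = as.integer(fn),
    fp_rate = 0, fn_rate = 5 * fn
  )
  # TMPM with 1 of 20 false negatives validates at its 10 ug/kg spike, below MRL 50
  d <- decide_ccbeta(err("TMPM", 1), panel_analyte(p, "TMPM"), cfg)
  expect_equal(d$decision, "validated")
  expect_equal(d$cc_beta, 10)
  expect_true(d$below_mrl)
  # SDIM with 0 false negatives validates at 20 ug/kg
  d2 <- decide_ccbeta(err("SDIM", 0), panel_analyte(p, "SDIM"), cfg)
  expect_equal(d2$cc_beta, 20)
  # 2 of 20 exceeds the allowance: escalate, no CCbeta
  d3 <- decide_ccbeta(err("SDZ", 2), panel_analyte(p, "SDZ"), cfg)
  expect_equal(d3$decision, "escalate")
  expect_true(is.na(d3$cc_beta))
  # prohibited substance is judged against its screening target
  d4 <- decide_ccbeta(err("DAP", 1), panel_analyte(p, "DAP"), cfg)
  expect_equal(d4$cc_beta, 20)
  expect_true(d4$below_mrl)
  # consistency errors
  expect_error(decide_ccbeta(err("SDZ", 1), panel_analyte(p, "TMPM"), cfg),
               "mismatch")
  bad <- err("SDZ", 1); bad$cutoff_rule <- "T"
  expect_error(decide_ccbeta(bad, panel_analyte(p, "SDZ"), cfg), "Fm")
})

test_that("validate_panel reproduces the full per-analyte report structure", {
  p <- default_panel()
  v <- simulate_validation_cohort(p, seed = 1)
  rep <- validate_panel(v, p)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$cutoffs), 15)
  expect_equal(nrow(rep$errors), 30)   # both rules per analyte
  expect_equal(nrow(rep$ccbeta), 15)
  # exact identities given the underlying means/SDs
  expect_equal(rep$cutoffs$t_value,
               rep$cutoffs$blank_mean - 1.6 * rep$cutoffs$blank_sd)
  expect_equal(rep$cutoffs$fm_value,
               rep$cutoffs$spiked_mean + 1.64 * rep$cutoffs$spiked_sd)
  expect_equal(rep$cutoffs$valid, rep$cutoffs$t_value > rep$cutoffs$fm_value)
  expect_equal(rep$cutoffs$chosen_cutoff, rep$cutoffs$fm_value)
  # rule choice is a runtime parameter
  rep_t <- validate_panel(v, p, cutoff_rule = "T")
  expect_equal(rep_t$cutoffs$chosen_cutoff, rep_t$cutoffs$t_value)
  expect_equal(rep_t$cutoffs$t_value, rep$cutoffs$t_value)
  # missing cohort errors name the analyte
  expect_error(validate_panel(v[v$analyte != "SQX", ], p), "SQX")
})

test_that("default cohorts validate every analyte over many seeds", {
  p <- default_panel()
  ok_valid <- ok_validated <- logical(30)
  for (s in seq_len(30)) {
    rep <- validate_panel(simulate_validation_cohort(p, seed = s), p)
    ok_valid[s] <- rep$summary$all_valid
    ok_validated[s] <- rep$summary$all_validated
  }
  expect_true(all(ok_valid))            # T > Fm for all analytes, every seed
  expect_gte(mean(ok_validated), 0.9)   # at most one false compliant each
})

test_that("heavily overlapping cohorts are reported invalid, not validated away", {
  p <- default_panel()
  v <- simulate_validation_cohort(p, noise = noise_model(cv = 1.0), seed = 6)
  rep <- validate_panel(v, p)
  expect_true(any(!rep$cutoffs$valid))
})
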