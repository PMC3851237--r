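test_that("noiseless cosines are recovered exactly at the study time points", {
  cases <- expand.grid(mesor = c(0.5, 1), amplitude = c(0.2, 0.5),
                       peak = c(0, 4, 10.5, 23))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    y <- cosine_series(cs$mesor, cs$amplitude, cs$peak)
    fit <- fit_cosinor(study_timepoints, y)
    expect_equal(fit$mesor, cs$mesor, tolerance = 1e-9)
    expect_equal(fit$amplitude, cs$amplitude, tolerance = 1e-9)
    expect_equal(fit$acrophase_deg, (cs$peak %% 24) * 15, tolerance = 1e-7)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("a peak at 4 h maps to a 60 degree acrophase", {
  y <- cosine_series(1, 0.5, 4)
  expect_equal(y[study_timepoints == 4], 1.5)
  fit <- fit_cosinor(study_timepoints, y)
  expect_equal(fit$acrophase_deg, 60, tolerance = 1e-9)
})

test_that("constant series yield zero amplitude and no detected rhythm", {
  fit <- fit_cosinor(study_timepoints, rep(0.7, 6))
  expect_equal(fit$amplitude, 0, tolerance = 1e-12)
  expect_equal(fit$p_zero_amplitude, 1)
  expect_equal(fit$significance_class, "none")
})

test_that("acrophase is equivariant under time shifts", {
  set.seed(42)
  for (i in 1:20) {
    peak <- stats::runif(1, 0, 24)
    shift <- stats::runif(1, -12, 12)
    f1 <- fit_cosinor(study_timepoints, cosine_series(1, 0.4, peak))
    f2 <- fit_cosinor(study_timepoints, cosine_series(1, 0.4, peak + shift))
    delta <- (f2$acrophase_deg - f1$acrophase_deg) %% 360
    expect_equal(delta, (shift * 15) %% 360, tolerance = 1e-6)
  }
})

test_that("amplitude is non-negative and the mesor absorbs constants", {
  set.seed(7)
  y <- cosine_series(0.6, 0.3, 9) + stats::rnorm(6, 0, 0.05)
  f1 <- fit_cosinor(study_timepoints, y)
  f2 <- fit_cosinor(study_timepoints, y + 2.5)
  expect_gte(f1$amplitude, 0)
  expect_equal(f2$mesor, f1$mesor + 2.5, tolerance = 1e-9)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-9)
  expect_equal(f2$acrophase_deg, f1$acrophase_deg, tolerance = 1e-9)
})

test_that("zero-amplitude F-test matches its definition and flags degeneracy", {
  # direct check of the F statistic against stats::pf
  zt <- zero_amplitude_test(model_ss = 3, resid_ss = 1.5, n = 18)
  f <- (3 / 2) / (1.5 / 15)
  expect_equal(zt$statistic, f)
  expect_equal(zt$p_value, stats::pf(f, 2, 15, lower.tail = FALSE))

  # huge amplitude vs noise: p tends to 0
  y <- cosine_series(1, 50, 4) + c(0.01, -0.01, 0.01, -0.01, 0.01, -0.01)
  expect_lt(fit_cosinor(study_timepoints, y)$p_zero_amplitude, 1e-8)

  # n = 4 exact fit: residual df exhausted, flagged
  t4 <- c(1, 4, 10, 16)
  f4 <- fit_cosinor(t4, cosine_series(1, 0.5, 4, times = t4))
  expect_true(f4$flagged)
  expect_equal(f4$p_zero_amplitude, .Machine$double.xmin)

  expect_error(fit_cosinor(c(1, 4, 10), c(1, 2, 3)), "4 distinct")
  expect_error(fit_cosinor(c(1, 1, 4, 4, 10, 10), rep(1, 6)), "4 distinct")
})

test_that("acrophase formatting rounds minutes and carries at 60", {
  expect_equal(acrophase_format(60.7), "60° 42′")
  expect_equal(acrophase_format(0), "0° 00′")
  expect_equal(acrophase_format(359.9999), "0° 00′")
  expect_equal(acrophase_format(45), "45° 00′")
  expect_error(acrophase_format(360), "\\[0, 360\\)")
})

test_that("rhythm table covers every gene-condition pair and recovers phases", {
  genes <- paste0("CG", 1:7)
  rp <- random_rhythm_params(genes, noise_sd = 0.05, seed = 5)
  rp$amplitude <- pmax(rp$amplitude, 0.2) # keep rhythms detectable
  ts <- gen_timeseries(rp, n_replicates = 3, seed = 6)
  rt <- rhythm_table(ts$series)
  expect_equal(nrow(rt), 21) # 7 genes x 3 conditions

  merged <- merge(rt, rp, by = c("gene", "condition"))
  dphi <- abs(merged$acrophase_deg.x - merged$acrophase_deg.y)
  dphi <- pmin(dphi, 360 - dphi)
  expect_lt(max(dphi), 15)

  # byte-identical on identical input
  expect_identical(rt, rhythm_table(ts$series))

  polar <- polarogram_table(rt)
  expect_equal(nrow(polar), 21)
  expect_equal(polar$radius, rt$amplitude)

  # missing series are reported, not dropped
  short <- ts$series[!(ts$series$gene == "CG1" &
                         ts$series$condition == "control" &
                         ts$series$time_h > 4), ]
  rt2 <- rhythm_table(short)
  expect_equal(rt2$significance[rt2$gene == "CG1" &
                                  rt2$condition == "control"], "no_fit")
})

test_that("replicate averaging is available as a switch", {
  rp <- random_rhythm_params("G1", conditions = "control", noise_sd = 0.1,
                             seed = 9)
  ts <- gen_timeseries(rp, n_replicates = 4, seed = 10)
  rt_rep <- rhythm_table(ts$series)
  rt_avg <- rhythm_table(ts$series, average_replicates = TRUE)
  expect_equal(rt_rep$n, 24)
  expect_equal(rt_avg$n, 6)
  # point estimates agree under a balanced design; inference differs
  expect_equal(rt_avg$mesor, rt_rep$mesor, tolerance = 1e-9)
  expect_equal(rt_avg$amplitude, rt_rep$amplitude, tolerance = 1e-9)
})
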