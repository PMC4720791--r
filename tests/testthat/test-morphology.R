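test_that("Holm-Bonferroni implements the step-down rule", {
  # hand-worked: 0.001 <= .05/3, 0.02 <= .05/2, 0.04 <= .05/1 -> all rejected
  res <- holm_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_true(all(res$reject))
  # step-down stops at the first failure
  res2 <- holm_bonferroni(c(0.001, 0.03, 0.04), alpha = 0.05)
  expect_equal(res2$reject, c(TRUE, FALSE, FALSE))
  expect_false(any(holm_bonferroni(rep(1, 5))$reject))
  expect_equal(holm_bonferroni(0.04)$reject, TRUE)
  expect_equal(holm_bonferroni(0.06)$reject, FALSE)
  # rejection set is monotone in the p-value ordering
  set.seed(1)
  for (i in 1:20) {
    p <- runif(15)^2
    r <- holm_bonferroni(p)
    if (any(r$reject)) expect_true(all(r$reject[p <= max(p[r$reject])]))
  }
  expect_error(holm_bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("significance profile matches stats::t.test and flags injected negativity", {
  fs <- 100
  set.seed(42)
  # high-SNR negativity on [-1, 1] s over 40 trials
  n_tr <- 40
  tt <- -3 + (seq_len(9 * fs) - 1) / fs
  bump <- -8 * (tt > -1 & tt < 1)
  x <- matrix(rnorm(n_tr * length(tt), sd = 1.5), n_tr, byrow = TRUE) +
    matrix(bump, n_tr, length(tt), byrow = TRUE)
  ep <- new_epoch_set(x, fs)
  prof <- mrcp_significance_profile(ep)
  expect_equal(nrow(prof), 80)
  mid <- prof$segment_center_s > -0.5 & prof$segment_center_s < 0.5
  expect_true(all(prof$significant[mid]))
  early <- prof$segment_center_s < -2.5 + 1e-9 &
    prof$segment_center_s > -3
  expect_false(any(prof$significant[early]))

  # dual route: p-values agree with stats::t.test on a few segments
  ref_mean <- rowMeans(x[, tt >= -3 & tt < -2])
  for (s in c(-1.5, 0.05, 4.2)) {
    seg_mean <- rowMeans(x[, tt >= s & tt < s + 0.1])
    p_ref <- t.test(seg_mean, ref_mean, paired = TRUE)$p.value
    row <- which.min(abs(prof$segment_center_s - (s + 0.05)))
    expect_equal(prof$p_value[row], p_ref, tolerance = 1e-12)
  }
})

test_that("identical segment and reference values give p = 1 and no rejections", {
  fs <- 50
  base <- rnorm(10)
  # every column repeats the same per-trial values as the reference interval
  x <- matrix(rep(base, times = 9 * fs), nrow = 10)
  ep <- new_epoch_set(x, fs)
  prof <- mrcp_significance_profile(ep)
  expect_true(all(prof$p_value == 1))
  expect_false(any(prof$significant))
  expect_error(mrcp_significance_profile(new_epoch_set(x[1, , drop = FALSE], fs)),
               "2 trials")
})

test_that("Welch machinery concentrates and scales power correctly", {
  fs <- 120
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  psd <- welch_psd(x, fs)
  expect_equal(psd$freq_hz[which.max(psd$power)], 20)
  # unit-amplitude sinusoid has total band power 1/2 (Parseval)
  expect_equal(sum(psd$power) * diff(psd$freq_hz)[1], 0.5, tolerance = 0.05)
  # density scaling recovers white-noise variance
  set.seed(3)
  w <- rnorm(length(t), sd = 2)
  psdw <- welch_psd(w, fs)
  expect_equal(sum(psdw$power) * diff(psdw$freq_hz)[1], 4, tolerance = 0.15)
  expect_error(welch_psd(rnorm(50), fs), "shorter")
})

test_that("the time-frequency map localizes a sinusoid and handles degenerate input", {
  fs <- 100
  n_tr <- 6
  tt <- -3 + (seq_len(9 * fs) - 1) / fs
  x <- matrix(sin(2 * pi * 20 * tt), n_tr, length(tt), byrow = TRUE) +
    matrix(rnorm(n_tr * length(tt), sd = 0.05), n_tr)
  map <- welch_tf_map(new_epoch_set(x, fs))
  expect_true(all(map$power >= 0))
  peak_per_t <- map$freq_hz[apply(map$power, 2, which.max)]
  expect_true(all(peak_per_t == 20))
  expect_equal(map$time_s, seq(-2.5, 5.5, by = 0.5))

  zero <- welch_tf_map(new_epoch_set(matrix(0, 3, 9 * fs), fs))
  expect_true(all(zero$power == 0))
  expect_error(erd_ers_percent(zero), "degenerate reference")
  expect_error(welch_tf_map(new_epoch_set(matrix(rnorm(60), 3), fs)),
               "shorter")
})

test_that("relative SMR power implements the ERD/ERS identities", {
  fs <- 100
  map <- welch_tf_map(new_epoch_set(matrix(rnorm(4 * 9 * fs), 4), fs))
  # A = R everywhere -> 0
  m0 <- map
  m0$power <- matrix(map$ref_power, length(map$freq_hz), length(map$time_s))
  expect_true(all(abs(erd_ers_percent(m0)$smr_pct) < 1e-12))
  # A = 2R -> +1 (100% ERS); A = 0 -> -1 (full ERD)
  m2 <- m0; m2$power <- 2 * m0$power
  expect_true(all(abs(erd_ers_percent(m2)$smr_pct - 1) < 1e-12))
  mz <- m0; mz$power <- 0 * m0$power
  expect_true(all(abs(erd_ers_percent(mz)$smr_pct + 1) < 1e-12))
  # scale invariance: scaling the epochs leaves SMR% unchanged
  sc <- map
  sc$power <- 7.3 * map$power
  sc$ref_power <- 7.3 * map$ref_power
  expect_equal(erd_ers_percent(sc)$smr_pct, erd_ers_percent(map)$smr_pct,
               tolerance = 1e-12)
})

test_that("bootstrap mask flags a known beta ERS and is deterministic", {
  fs <- 100
  n_tr <- 40
  tt <- -3 + (seq_len(9 * fs) - 1) / fs
  set.seed(8)
  carrier <- matrix(rnorm(n_tr * length(tt)), n_tr)
  bf <- signal::butter(4, c(16, 30) / (fs / 2), type = "pass")
  beta <- t(apply(carrier, 1, function(r) as.numeric(signal::filter(bf, r))))
  gain <- sqrt(1 + 1 * (tt > 0.5 & tt < 2.5))   # power doubles post-onset
  x <- beta * matrix(gain, n_tr, length(tt), byrow = TRUE) +
    matrix(rnorm(n_tr * length(tt), sd = 0.3), n_tr)
  map <- erd_ers_percent(welch_tf_map(new_epoch_set(x, fs)))
  masked <- bootstrap_mask(map, n_boot = 500, seed = 4)
  flags <- tidy(masked)
  # a doubled-power effect at n = 40 has ~80% per-point power, so require a
  # clear majority of the ERS block flagged, not unanimity
  ers <- flags$freq_hz >= 16 & flags$freq_hz <= 30 &
    flags$time_s > 0.5 & flags$time_s < 2.5
  expect_gt(mean(flags$significant[ers]), 0.6)
  pre <- flags$time_s < -0.5
  expect_lt(mean(flags$significant[pre]), 0.2)

  m2 <- bootstrap_mask(map, n_boot = 500, seed = 4)
  expect_identical(masked$mask, m2$mask)
  m3 <- bootstrap_mask(map, n_boot = 500, seed = 5)
  expect_false(identical(masked$mask, m3$mask))
  expect_error(bootstrap_mask(map, n_boot = 50), "100")
})
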