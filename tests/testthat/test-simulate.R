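test_that("MRCP template has the described morphology landmarks", {
  fs <- 200
  a <- 7.5

  bal <- mrcp_template("ballistic", a, fs)
  expect_equal(range(bal$time_s), c(-3, 6))
  # peak negativity of -amplitude at the cue
  expect_lt(abs(bal$time_s[which.min(bal$value_uv)]), 0.2)
  expect_equal(min(bal$value_uv), -a)
  # flat before the pre-onset fall and back at baseline by ~2 s
  expect_true(all(bal$value_uv[bal$time_s < -2] == 0))
  expect_true(all(abs(bal$value_uv[bal$time_s >= 2.5]) < 1e-12))

  rep <- mrcp_template("repetitive", a, fs)
  # identical pre-onset limb, sustained negativity late into the task
  expect_equal(rep$value_uv[rep$time_s <= 0], bal$value_uv[bal$time_s <= 0])
  expect_lt(rep$value_uv[which.min(abs(rep$time_s - 3.5))], -0.1 * a)
  expect_equal(rep$value_uv[length(rep$value_uv)], 0, tolerance = 1e-6)

  expect_true(all(mrcp_template("ballistic", 0, fs)$value_uv == 0))
  expect_error(mrcp_template("ballistic", -1, fs), "non-negative")
})

test_that("SMR modulation envelope reaches the configured ERD/ERS extremes", {
  fs <- 100
  beta <- smr_band("beta", 21, 8, erd_depth = 0.3, ers_gain = 2)
  prof <- smr_modulation_profile("ballistic", beta, fs)
  expect_equal(max(prof$gain), 2, tolerance = 1e-6)
  expect_gt(prof$time_s[which.max(prof$gain)], 0)
  expect_equal(min(prof$gain), 1 - 0.3, tolerance = 1e-6)
  expect_equal(prof$gain[prof$time_s < -2.5], rep(1, sum(prof$time_s < -2.5)))

  flat <- smr_band("x", 10, 4, erd_depth = 0, ers_gain = 1)
  expect_true(all(smr_modulation_profile("ballistic", flat, fs)$gain == 1))
  expect_true(all(smr_modulation_profile("repetitive", flat, fs)$gain == 1))
})

test_that("repetitive ERS peaks strictly later than ballistic for every band", {
  fs <- 100
  for (b in seq_len(nrow(default_smr_bands()))) {
    spec <- default_smr_bands()[b, ]
    if (spec$ers_gain <= 1) next
    pb <- smr_modulation_profile("ballistic", spec, fs)
    pr <- smr_modulation_profile("repetitive", spec, fs)
    expect_gt(pr$time_s[which.max(pr$gain)], pb$time_s[which.max(pb$gain)])
  }
  # the delay also holds for an arbitrary custom band
  spec <- smr_band("g", 35, 6, erd_depth = 0.2, ers_gain = 1.5,
                   ers_onset_s = 0.3, ers_duration_s = 1)
  pb <- smr_modulation_profile("ballistic", spec, fs)
  pr <- smr_modulation_profile("repetitive", spec, fs)
  expect_gt(pr$time_s[which.max(pr$gain)], pb$time_s[which.max(pb$gain)])
})

test_that("background noise has a 1/f pink component and is reproducible", {
  fs <- 120
  # pure pink, long stretch: log-log PSD slope over 1-40 Hz near -1
  x <- background_noise(400, 1, list(pink_uv = 1, white_uv = 0, mixing = 0),
                        fs, seed = 42)
  psd <- welch_psd(as.numeric(x), fs, segment_s = 2)
  sel <- psd$freq_hz >= 1 & psd$freq_hz <= 40
  slope <- coef(lm(log(power) ~ log(freq_hz), data = psd[sel, ]))[2]
  expect_lt(abs(slope + 1), 0.2)

  zero <- background_noise(5, 3, list(pink_uv = 0, white_uv = 0, mixing = 0),
                           fs, seed = 1)
  expect_true(all(zero == 0))

  a <- background_noise(5, 3, list(pink_uv = 2, white_uv = 1, mixing = 0.5),
                        fs, seed = 7)
  b <- background_noise(5, 3, list(pink_uv = 2, white_uv = 1, mixing = 0.5),
                        fs, seed = 7)
  expect_identical(a, b)
})

test_that("generated sessions have the stated trial structure and bookkeeping", {
  rec <- quick_session(n_runs = 3, trials_per_run = 20, seed = 9,
                       sampling_rate = 60)
  cues <- cue_times(rec)
  expect_length(cues, 60)
  # inter-cue spacing within a run equals the summed phase durations (14 s)
  expect_true(all(abs(diff(cues)[-c(20, 40)] - 14) < 1e-9))
  expect_equal(sum(rec$events$label == "run_start"), 3)
  # first cue sits after idle + focus + preparation
  expect_equal(cues[1], 10)
  expect_equal(attr(rec, "task_kind"), "ballistic")
})

test_that("a noise-free session recovers the injected template through Eq. 1 epoching", {
  fs <- 120
  a <- 6
  rec <- quick_session(n_runs = 1, trials_per_run = 2, seed = 5,
                       sampling_rate = fs, mrcp_amplitude = a,
                       noise = no_noise(), smr_bands = no_smr())
  ep <- extract_epochs(large_laplacian(rec))
  tpl <- mrcp_template("ballistic", a, fs)$value_uv[seq_len(9 * fs)]
  expect_lt(max(abs(t(ep$data) - tpl)) / a, 1e-9)
})

test_that("session generation is a pure function of config and seed", {
  cfg <- sim_config("repetitive", sampling_rate = 60, n_runs = 2,
                    trials_per_run = 2, seed = 123)
  r1 <- generate_session(cfg)
  r2 <- generate_session(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$events, r2$events)
  r3 <- generate_session(sim_config("repetitive", sampling_rate = 60,
                                    n_runs = 2, trials_per_run = 2,
                                    seed = 124))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_runs = 0), "n_runs")
  expect_error(sim_config(mrcp_amplitude = -2), "non-negative")
  expect_error(sim_config(noise = list(pink_uv = -1, white_uv = 0, mixing = 0)),
               "noise")
  expect_error(smr_band("b", 20, 5, erd_depth = 1.5), "erd_depth")
  expect_error(smr_band("b", 20, 5, ers_gain = 0.5), "ers_gain")
  expect_error(background_noise(-1, 2, no_noise(), 100), "duration")
})
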