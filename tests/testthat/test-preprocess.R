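make_rec <- function(samples, fs = 100) {
  new_eeg_recording(samples, names(default_spatial_profile()), fs,
                    tibble::tibble(onset_s = numeric(0), label = character(0),
                                   run_index = integer(0)))
}

test_that("canonical bands carry exactly the printed edges", {
  tab <- band_definitions()
  expect_equal(tab$band, c("MRCP", "Theta", "Alpha", "Beta", "Gamma", "Full"))
  expect_equal(tab$low, c(0.05, 4, 8, 16, 31, 0.05))
  expect_equal(tab$high, c(3, 7, 15, 30, 40, 40))
  expect_error(band_spec("nope"), "unknown band")
  expect_error(band_spec("bad", 5, 2), "low < high")
})

test_that("band-pass filter matches its analytic magnitude response", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- matrix(rep(sin(2 * pi * 10 * t), 9), nrow = 9, byrow = TRUE)
  rec <- make_rec(x, fs)

  steady_amp <- function(filtered) {
    y <- filtered$samples[1, ]
    max(abs(y[(length(y) - 5 * fs):length(y)]))
  }
  # reference gain from the analytic transfer function at f Hz
  gain_at <- function(low, high, f) {
    bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))
  }
  in_band <- bandpass_filter(rec, band_spec("Alpha"), mode = "causal")
  expect_equal(steady_amp(in_band), gain_at(8, 15, 10), tolerance = 0.01)
  out_band <- bandpass_filter(rec, band_spec("Beta"), mode = "causal")
  expect_equal(steady_amp(out_band), gain_at(16, 30, 10), tolerance = 0.05)
  expect_lt(steady_amp(out_band), 0.2)

  # DC offset is rejected by any passband above 0 Hz
  dc <- make_rec(matrix(5, 9, 20 * fs), fs)
  fdc <- bandpass_filter(dc, band_spec("Alpha"), mode = "causal")
  expect_lt(max(abs(fdc$samples[1, (19 * fs):(20 * fs)])), 1e-6 * 5)

  expect_error(bandpass_filter(rec, band_spec("hf", 10, 150)), "Nyquist")
})

test_that("zero-phase mode introduces no group delay", {
  fs <- 200
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  pulse <- sin(2 * pi * 10 * t) * exp(-((t - 10)^2) / 0.5)
  rec <- make_rec(matrix(rep(pulse, 9), nrow = 9, byrow = TRUE), fs)
  y <- bandpass_filter(rec, band_spec("Alpha"), mode = "zero_phase")$samples[1, ]
  cc <- ccf(y, pulse, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("the large Laplacian is exactly Cz minus the neighbour mean", {
  fs <- 100
  set.seed(1)
  x <- matrix(rnorm(9 * 1000), 9, 1000)
  rec <- make_rec(x, fs)
  v <- large_laplacian(rec)
  expect_equal(v$samples, x[1, ] - colMeans(x[-1, ]), tolerance = 1e-14)

  # common-mode rejection and pure-centre passthrough
  cm <- make_rec(matrix(3.7, 9, 50), fs)
  expect_true(all(large_laplacian(cm)$samples == 0))
  cz <- matrix(0, 9, 50); cz[1, ] <- 8
  expect_true(all(large_laplacian(make_rec(cz, fs))$samples == 8))

  # linearity
  y <- matrix(rnorm(9 * 1000), 9, 1000)
  lhs <- large_laplacian(make_rec(2 * x + 3 * y, fs))$samples
  rhs <- 2 * large_laplacian(make_rec(x, fs))$samples +
    3 * large_laplacian(make_rec(y, fs))$samples
  expect_equal(lhs, rhs, tolerance = 1e-12)

  bad <- rec
  bad$channel_labels <- bad$channel_labels[-5]
  bad$samples <- bad$samples[-5, ]
  expect_error(large_laplacian(bad,
                               neighbors = setdiff(rec$channel_labels, "Cz")),
               "C3")
  expect_error(large_laplacian(bad), "8 neighbour")
})

test_that("epoch extraction respects spans, counts and boundaries", {
  fs <- 100
  n <- 40 * fs
  v <- list(samples = rnorm(n), sampling_rate = fs)
  ep <- extract_epochs(v, cues = c(10, 25))
  expect_equal(dim(ep$data), c(2, 9 * fs))
  expect_equal(range(ep$times), c(-3, 6 - 1 / fs))
  expect_equal(ep$data[1, ], v$samples[(7 * fs + 1):(16 * fs)])
  expect_error(extract_epochs(v, cues = 1), "cue 1")
  expect_error(extract_epochs(v, cues = 39), "cue 1")
  expect_equal(nrow(extract_epochs(v, cues = c(5, 15, 30))$data), 3)
})

test_that("epoching commutes with the Laplacian", {
  rec <- quick_session(n_runs = 1, trials_per_run = 2, seed = 2,
                       sampling_rate = 60)
  cues <- cue_times(rec)
  # Laplacian then epochs
  e1 <- extract_epochs(large_laplacian(rec), cues)$data
  # per-channel epochs then Laplacian across epoch matrices
  ch_ep <- lapply(seq_len(9), function(ch) {
    extract_epochs(list(samples = rec$samples[ch, ],
                        sampling_rate = rec$sampling_rate), cues)$data
  })
  e2 <- ch_ep[[1]] - Reduce(`+`, ch_ep[-1]) / 8
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("sliding windows follow the causal 2 s / 0.1 s grid with half-open labels", {
  fs <- 100
  v <- list(samples = rnorm(9 * fs), sampling_rate = fs)
  ws <- sliding_windows(v, cues = numeric(0))
  expect_equal(nrow(ws$windows), floor((9 - 2) / 0.1) + 1)  # 71
  expect_equal(ncol(ws$windows), 2 * fs)
  expect_equal(diff(ws$info$time_s)[1], 0.1)

  v2 <- list(samples = rnorm(30 * fs), sampling_rate = fs)
  ws2 <- sliding_windows(v2, cues = 15)
  lab <- function(t) ws2$info$label[which.min(abs(ws2$info$time_s - t))]
  expect_equal(as.character(lab(15.5)), "signal")
  expect_equal(as.character(lab(17.0)), "noise")
  expect_equal(as.character(lab(14.1)), "signal")   # just inside (cue-1, cue+1]
  expect_equal(as.character(lab(14.0)), "noise")    # exactly cue-1 is outside
  expect_equal(as.character(lab(16.0)), "signal")   # exactly cue+1 is inside
  # exactly 20 signal windows for an isolated cue
  expect_equal(sum(ws2$info$label == "signal"), 20)
  # labels partition the windows
  expect_equal(sum(ws2$info$label == "signal") + sum(ws2$info$label == "noise"),
               nrow(ws2$windows))

  # disjoint tiling when step equals length
  ws3 <- sliding_windows(v2, cues = numeric(0), length_s = 2, step_s = 2)
  expect_equal(nrow(ws3$windows), 15)
  expect_equal(as.numeric(t(ws3$windows)), v2$samples)

  expect_error(sliding_windows(list(samples = rnorm(50), sampling_rate = fs),
                               cues = numeric(0)), "shorter")
})
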