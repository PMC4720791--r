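hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# One-sided Welch PSD of each row of `x` (a windows-by-samples matrix).
# Segments of `nperseg` samples advanced by `nstep`, Hamming-tapered,
# density scaling (power integrates over Hz to the signal variance).
welch_psd_matrix <- function(x, sampling_rate, nperseg, nstep) {
  stopifnot(is.matrix(x), ncol(x) >= nperseg)
  w <- hamming_window(nperseg)
  starts <- seq(1L, ncol(x) - nperseg + 1L, by = nstep)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nperseg - 1L), drop = FALSE] *
      matrix(w, nrow(x), nperseg, byrow = TRUE)
    f <- stats::mvfft(t(seg))
    acc <- acc + t(Mod(f[seq_len(nfreq), , drop = FALSE])^2)
  }
  scale <- 1 / (sampling_rate * sum(w^2) * length(starts))
  psd <- acc * scale
  # one-sided: double all bins except DC (and Nyquist when nperseg is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  psd <- sweep(psd, 2, dbl, "*")
  list(freq_hz = (seq_len(nfreq) - 1L) * sampling_rate / nperseg, power = psd)
}

#' Welch power spectral density
#'
#' Hamming-tapered Welch estimate with density scaling: summing
#' `power * df` over frequency recovers the signal variance.
#'
#' @param x Numeric vector.
#' @param sampling_rate Hz.
#' @param segment_s Segment length in seconds (default 1, giving 1-Hz
#'   resolution at integer sampling rates).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `freq_hz` and `power`.
#' @export
welch_psd <- function(x, sampling_rate, segment_s = 1, overlap = 0.5) {
  nperseg <- round(segment_s * sampling_rate)
  if (length(x) < nperseg) {
    stop("signal shorter than one Welch segment", call. = FALSE)
  }
  nstep <- max(1L, round(nperseg * (1 - overlap)))
  out <- welch_psd_matrix(matrix(x, 1L), sampling_rate, nperseg, nstep)
  tibble::tibble(freq_hz = out$freq_hz, power = as.numeric(out$power))
}

#' Holm-Bonferroni step-down correction
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Familywise significance level.
#' @return A tibble with `p_value`, `p_adjusted` (Holm) and `reject`.
#' @examples
#' holm_bonferroni(c(0.001, 0.02, 0.04))
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "holm")
  tibble::tibble(p_value = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' MRCP significance profile
#'
#' For each 0.1-s segment of the epoch outside the reference interval, a
#' paired t-test across trials compares the segment's per-trial mean
#' amplitude with the per-trial mean over the reference interval;
#' Holm-Bonferroni is applied jointly over all segments.
#'
#' @param epochs An `epoch_set` of virtual-Cz trials.
#' @param alpha Familywise significance level (default 0.05).
#' @param segment_s Segment length in seconds (default 0.1).
#' @return A tibble of class `mrcp_profile` with columns
#'   `segment_center_s`, `mean_diff_uv` (trial-mean segment minus reference
#'   amplitude), `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
mrcp_significance_profile <- function(epochs, alpha = 0.05, segment_s = 0.1) {
  x <- epochs$data
  if (nrow(x) < 2L) {
    stop("at least 2 trials are required for the paired t-test", call. = FALSE)
  }
  tt <- epochs$times
  ref <- epochs$reference_interval
  ref_mean <- rowMeans(x[, tt >= ref[1] & tt < ref[2], drop = FALSE])
  n_seg <- floor(ncol(x) / epochs$sampling_rate / segment_s)
  starts <- min(tt) + (seq_len(n_seg) - 1L) * segment_s
  keep <- !(starts < ref[2] & (starts + segment_s) > ref[1])
  starts <- starts[keep]
  seg_mean <- vapply(starts, function(s) {
    rowMeans(x[, tt >= s & tt < s + segment_s, drop = FALSE])
  }, numeric(nrow(x)))
  d <- seg_mean - ref_mean
  nt <- nrow(x)
  md <- colMeans(d)
  sd_d <- apply(d, 2, stats::sd)
  tstat <- md / (sd_d / sqrt(nt))
  p <- 2 * stats::pt(-abs(tstat), df = nt - 1)
  p[sd_d == 0 & md == 0] <- 1          # degenerate identical pairs: no evidence
  hb <- holm_bonferroni(p, alpha)
  out <- tibble::tibble(
    segment_center_s = starts + segment_s / 2,
    mean_diff_uv = md,
    statistic = tstat,
    p_value = p,
    p_adjusted = hb$p_adjusted,
    significant = hb$reject
  )
  class(out) <- c("mrcp_profile", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Time-frequency power map of an epoch set
#'
#' Per trial, 1-s Hamming-windowed periodograms slide across the epoch with
#' 0.5-s overlap; averaging across trials yields the absolute power
#' `A[f, t]`. The per-frequency reference power `R[f]` is the trial-averaged
#' power of the windows wholly inside the reference interval.
#'
#' @param epochs An `epoch_set`.
#' @param fmin,fmax Frequency range to retain, Hz.
#' @param window_s PSD window length, seconds (default 1: 1-Hz resolution).
#' @param overlap_s Window overlap, seconds (default 0.5).
#' @return A `tf_map`: list with `power` (freq x time), `ref_power`,
#'   `smr_pct` (filled by [erd_ers_percent()]), `mask` (filled by
#'   [bootstrap_mask()]), `freq_hz`, `time_s` (window centres),
#'   `trial_power` (trials x freq x time array), `reference_interval`.
#' @export
welch_tf_map <- function(epochs, fmin = 1, fmax = 40,
                         window_s = 1, overlap_s = 0.5) {
  fs <- epochs$sampling_rate
  tt <- epochs$times
  if (max(tt) - min(tt) < window_s) {
    stop("epoch shorter than one PSD window", call. = FALSE)
  }
  if (fmax >= fs / 2) stop("fmax must be below Nyquist", call. = FALSE)
  nperseg <- round(window_s * fs)
  nstep <- round((window_s - overlap_s) * fs)
  i_starts <- seq(1L, ncol(epochs$data) - nperseg + 1L, by = nstep)
  starts <- tt[i_starts]
  nfreq_all <- floor(nperseg / 2) + 1L
  freqs_all <- (seq_len(nfreq_all) - 1L) * fs / nperseg
  fsel <- which(freqs_all >= fmin & freqs_all <= fmax)
  ntr <- nrow(epochs$data)
  trial_power <- array(NA_real_, c(ntr, length(fsel), length(starts)))
  for (j in seq_along(starts)) {
    i0 <- i_starts[j]
    seg <- epochs$data[, i0:(i0 + nperseg - 1L), drop = FALSE]
    ps <- welch_psd_matrix(seg, fs, nperseg, nperseg)  # single segment
    trial_power[, , j] <- ps$power[, fsel, drop = FALSE]
  }
  power <- apply(trial_power, c(2, 3), mean)
  ref <- epochs$reference_interval
  ref_cols <- which(starts >= ref[1] - 1e-9 & starts + window_s <= ref[2] + 1e-9)
  if (!length(ref_cols)) {
    stop("no PSD window lies wholly inside the reference interval", call. = FALSE)
  }
  ref_power <- rowMeans(power[, ref_cols, drop = FALSE])
  structure(list(power = power, ref_power = ref_power, smr_pct = NULL,
                 mask = NULL, freq_hz = freqs_all[fsel],
                 time_s = starts + window_s / 2,
                 trial_power = trial_power, ref_cols = ref_cols,
                 reference_interval = ref),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d freqs (%g-%g Hz) x %d times (%.2f..%.2f s), %d trials\n",
              length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              length(x$time_s), min(x$time_s), max(x$time_s),
              dim(x$trial_power)[1]))
  if (!is.null(x$smr_pct)) cat("  relative SMR power: filled\n")
  if (!is.null(x$mask)) cat(sprintf("  bootstrap mask: %d significant points\n",
                                    sum(x$mask)))
  invisible(x)
}

#' Relative SMR power (ERD/ERS percentage)
#'
#' Fills the map's relative power `(A[f, t] - R[f]) / R[f]`. Positive values
#' are ERS (power above baseline), negative values ERD.
#'
#' @param map A `tf_map` from [welch_tf_map()].
#' @return The map with `smr_pct` filled (dimensionless fraction; multiply by
#'   100 for percent).
#' @export
erd_ers_percent <- function(map) {
  if (any(map$ref_power <= 0)) {
    bad <- map$freq_hz[map$ref_power <= 0]
    stop("degenerate reference power at ", paste(bad, collapse = ", "),
         " Hz", call. = FALSE)
  }
  map$smr_pct <- sweep(sweep(map$power, 1, map$ref_power, "-"),
                       1, map$ref_power, "/")
  map
}

#' Bootstrap significance mask of a time-frequency map
#'
#' For each time-frequency point, the per-trial difference between the
#' point's power and the trial's reference power at that frequency is the
#' exchangeable unit. Trial indices are resampled with replacement (drawn
#' once per replicate and shared across the whole grid, so absolute and
#' reference power are recomputed coherently) and a symmetric studentized
#' (bootstrap-t) confidence interval of the mean difference is formed, using
#' the bootstrap quantile of the absolute studentized statistic; the point
#' is flagged when that interval excludes zero at level `alpha`.
#' Single-trial periodogram powers are strongly non-Gaussian, and the
#' symmetric studentized interval keeps the per-point false-flag rate at its
#' nominal level where a percentile interval does not.
#'
#' @param map A `tf_map`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Integer seed for the resampling.
#' @return The map with `mask` filled (logical freq x time matrix).
#' @export
bootstrap_mask <- function(map, n_boot = 1000, alpha = 0.05, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  ntr <- dim(map$trial_power)[1]
  if (ntr < 2) stop("at least 2 trials are required", call. = FALSE)
  nf <- dim(map$trial_power)[2]
  nt <- dim(map$trial_power)[3]
  flat <- matrix(map$trial_power, nrow = ntr)           # trials x (freq*time)
  rtrial <- apply(map$trial_power[, , map$ref_cols, drop = FALSE],
                  c(1, 2), mean)                        # trials x freq
  d <- flat - matrix(rtrial, ntr, nf * nt)              # per-trial differences
  m0 <- colMeans(d)
  se0 <- sqrt(apply(d, 2, stats::var) / ntr)
  tcrit <- withr::with_seed(seed, {
    wts <- matrix(0, n_boot, ntr)
    for (b in seq_len(n_boot)) {
      wts[b, ] <- tabulate(sample.int(ntr, ntr, replace = TRUE), ntr) / ntr
    }
    mb <- wts %*% d
    qb <- wts %*% d^2
    vb <- pmax(qb - mb^2, 0) * ntr / (ntr - 1)
    tb <- abs(sweep(mb, 2, m0) / sqrt(vb / ntr))
    tb[!is.finite(tb)] <- 0
    apply(tb, 2, stats::quantile, probs = 1 - alpha)
  })
  flag <- abs(m0) > se0 * tcrit
  flag[se0 == 0] <- m0[se0 == 0] != 0      # no sampling variability at all
  map$mask <- matrix(flag, nf, nt)
  map
}

#' Tidy a time-frequency map
#'
#' @param x A `tf_map`.
#' @param ... Unused.
#' @return A tibble with one row per time-frequency point: `freq_hz`,
#'   `time_s`, `power`, and where filled `smr_pct` and `significant`.
#' @export
tidy.tf_map <- function(x, ...) {
  grid <- tidyr::expand_grid(time_s = x$time_s, freq_hz = x$freq_hz)
  ij <- cbind(match(grid$freq_hz, x$freq_hz), match(grid$time_s, x$time_s))
  grid$power <- as.numeric(x$power[ij])
  if (!is.null(x$smr_pct)) grid$smr_pct <- as.numeric(x$smr_pct[ij])
  if (!is.null(x$mask)) grid$significant <- as.logical(x$mask[ij])
  grid
}
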