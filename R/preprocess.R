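#' Band-pass filter a recording
#'
#' Second-order Butterworth band-pass applied per channel. `causal` mode runs
#' a single forward pass and is used on the detection path, where every sample
#' must be computable from the past; `zero_phase` runs forward-backward
#' (`signal::filtfilt`) and is used on the morphology path where zero group
#' delay matters for averaging.
#'
#' @param recording An `eeg_recording`.
#' @param band One-row band tibble (see [band_spec()]) or a band name.
#' @param mode `"causal"` or `"zero_phase"`.
#' @return A filtered `eeg_recording`.
#' @export
bandpass_filter <- function(recording, band, mode = c("causal", "zero_phase")) {
  mode <- match.arg(mode)
  if (is.character(band)) band <- band_spec(band)
  nyq <- recording$sampling_rate / 2
  if (band$high >= nyq) {
    stop("band high edge (", band$high, " Hz) must be below Nyquist (",
         nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(2, c(band$low, band$high) / nyq, type = "pass")
  flt <- if (mode == "causal") {
    function(x) as.numeric(signal::filter(bf, x))
  } else {
    function(x) as.numeric(signal::filtfilt(bf, x))
  }
  out <- recording
  out$samples <- t(apply(recording$samples, 1, flt))
  rownames(out$samples) <- recording$channel_labels
  out
}

#' Large Laplacian spatial filter (virtual Cz)
#'
#' Derives the single virtual channel `center - mean(eight neighbours)`,
#' the large surface-Laplacian montage that sharpens focal activity under the
#' centre electrode and cancels activity common to the surrounding ring.
#'
#' @param recording An `eeg_recording` containing all nine channels.
#' @param center Centre channel label (default `"Cz"`).
#' @param neighbors Labels of the eight surrounding channels; defaults to all
#'   other channels of the standard montage.
#' @return A `virtual_channel`: list with `samples`, `sampling_rate`,
#'   `events` (carried over), and `provenance`.
#' @export
large_laplacian <- function(recording, center = "Cz", neighbors = NULL) {
  if (is.null(neighbors)) {
    neighbors <- setdiff(recording$channel_labels, center)
  }
  if (length(neighbors) != 8L) {
    stop("large Laplacian needs exactly 8 neighbour channels", call. = FALSE)
  }
  missing <- setdiff(c(center, neighbors), recording$channel_labels)
  if (length(missing)) {
    stop("channel(s) missing from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- recording$samples[center, ] -
    colMeans(recording$samples[neighbors, , drop = FALSE])
  structure(list(samples = as.numeric(v),
                 sampling_rate = recording$sampling_rate,
                 events = recording$events,
                 provenance = list(center = center, neighbors = neighbors)),
            class = "virtual_channel")
}

#' @export
print.virtual_channel <- function(x, ...) {
  cat(sprintf("<virtual_channel> %s - mean(%s); %d samples @ %g Hz\n",
              x$provenance$center,
              paste(x$provenance$neighbors, collapse = ","),
              length(x$samples), x$sampling_rate))
  invisible(x)
}

#' Extract cue-locked epochs
#'
#' Cuts one segment per cue from a single-channel series, on a common time
#' axis relative to the cue (default -3..6 s). No baseline subtraction is
#' performed here; downstream stages reference against the declared
#' `reference_interval` themselves.
#'
#' The epoch span is half-open `[tmin, tmax)`, so a -3..6 s epoch holds
#' exactly `9 * sampling_rate` samples.
#'
#' @param virtual A `virtual_channel` (or any list with `samples` and
#'   `sampling_rate`).
#' @param cues Cue onset times in seconds; defaults to the `"task"` events
#'   carried by `virtual`.
#' @param tmin,tmax Epoch span relative to the cue, seconds.
#' @param reference_interval Two-element baseline interval, seconds.
#' @return An `epoch_set`: list with `data` (trials x samples matrix),
#'   `times` (seconds relative to cue), `sampling_rate`,
#'   `reference_interval`.
#' @export
extract_epochs <- function(virtual, cues = NULL, tmin = -3, tmax = 6,
                           reference_interval = c(-3, -2)) {
  fs <- virtual$sampling_rate
  if (is.null(cues)) cues <- virtual$events$onset_s[virtual$events$label == "task"]
  stopifnot(tmin < tmax,
            reference_interval[1] >= tmin, reference_interval[2] <= tmax)
  n <- length(virtual$samples)
  i0 <- round(tmin * fs)
  i1 <- round(tmax * fs) - 1L
  times <- seq(i0, i1) / fs
  rows <- lapply(seq_along(cues), function(k) {
    cs <- round(cues[k] * fs) + 1L
    idx <- (cs + i0):(cs + i1)
    if (idx[1] < 1L || idx[length(idx)] > n) {
      stop(sprintf("cue %d at %.3f s too close to the recording edge for a [%g, %g] s epoch",
                   k, cues[k], tmin, tmax), call. = FALSE)
    }
    virtual$samples[idx]
  })
  structure(list(data = do.call(rbind, rows), times = times,
                 sampling_rate = fs,
                 reference_interval = reference_interval),
            class = "epoch_set")
}

#' Construct an epoch set directly from a trials-by-samples matrix
#'
#' @param data Numeric matrix, trials in rows.
#' @param sampling_rate Hz.
#' @param tmin Time of the first column relative to the cue, seconds.
#' @param reference_interval Two-element baseline interval, seconds.
#' @return An `epoch_set`.
#' @export
new_epoch_set <- function(data, sampling_rate, tmin = -3,
                          reference_interval = c(-3, -2)) {
  stopifnot(is.matrix(data))
  times <- tmin + (seq_len(ncol(data)) - 1L) / sampling_rate
  structure(list(data = data, times = times, sampling_rate = sampling_rate,
                 reference_interval = reference_interval),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples @ %g Hz, t in [%.2f, %.2f] s, reference [%g, %g] s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              min(x$times), max(x$times),
              x$reference_interval[1], x$reference_interval[2]))
  invisible(x)
}

#' Causal sliding windows with signal/noise labels
#'
#' Segments a continuous stretch into windows of `length_s` advanced by
#' `step_s`, indexed by the absolute time of each window's trailing edge (the
#' causal convention: a window's time stamp refers only to already-observed
#' samples). A window is labelled `"signal"` when its trailing edge falls in
#' the half-open interval `(cue - 1, cue + 1]` s for some cue, otherwise
#' `"noise"`.
#'
#' @param virtual A `virtual_channel` (or compatible list); `t0` gives the
#'   absolute time of its first sample.
#' @param cues Cue onset times in seconds (absolute); defaults to the
#'   `"task"` events carried by `virtual`.
#' @param length_s Window length, seconds (default 2).
#' @param step_s Step between consecutive trailing edges, seconds
#'   (default 0.1).
#' @param t0 Absolute time of the first sample, seconds.
#' @param label_halfwidth_s Half-width of the signal-labelling interval
#'   around each cue, seconds (default 1).
#' @return A `window_set`: list with `windows` (n x window-samples matrix),
#'   `info` (tibble: `time_s` trailing-edge times, `label`), `sampling_rate`,
#'   `length_s`, `step_s`.
#' @export
sliding_windows <- function(virtual, cues = NULL, length_s = 2, step_s = 0.1,
                            t0 = 0, label_halfwidth_s = 1) {
  fs <- virtual$sampling_rate
  x <- virtual$samples
  if (is.null(cues)) cues <- virtual$events$onset_s[virtual$events$label == "task"]
  len <- round(length_s * fs)
  step <- round(step_s * fs)
  n <- length(x)
  if (n < len) stop("stretch shorter than one window", call. = FALSE)
  ends <- seq(len, n, by = step)            # trailing-edge sample indices
  windows <- t(vapply(ends, function(e) x[(e - len + 1L):e], numeric(len)))
  # integer-sample label test avoids floating-point boundary jitter
  cue_samp <- round((cues - t0) * fs)
  half <- round(label_halfwidth_s * fs)
  is_signal <- vapply(ends, function(e) {
    any(e > cue_samp - half & e <= cue_samp + half)
  }, logical(1))
  info <- tibble::tibble(
    time_s = t0 + ends / fs,
    label = factor(ifelse(is_signal, "signal", "noise"),
                   levels = c("signal", "noise", "excluded"))
  )
  structure(list(windows = windows, info = info, sampling_rate = fs,
                 length_s = length_s, step_s = step_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (step %g s) @ %g Hz; %d signal / %d noise\n",
              nrow(x$windows), x$length_s, x$step_s, x$sampling_rate,
              sum(x$info$label == "signal"), sum(x$info$label == "noise")))
  invisible(x)
}
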