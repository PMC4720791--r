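#' Time-series features: anti-aliased decimated window samples
#'
#' Each feature vector is the window's band-filtered virtual-Cz samples after
#' low-pass anti-aliasing and downsampling by `decimation_factor`. No
#' amplitude normalization is applied: the discriminant operates on the raw
#' microvolt scale.
#'
#' @param windows A `window_set`.
#' @param decimation_factor Integer >= 1. The conventional choice keeps ~40
#'   samples per 2-s window (`sampling_rate / 20`).
#' @param n_taps FIR anti-aliasing filter length (odd; default 31). Ignored
#'   when `decimation_factor` is 1, which returns the raw samples unchanged.
#' @return A `feature_set`: list with `x` (n x p feature matrix) and `info`
#'   (the window tibble: trailing-edge `time_s`, `label`).
#' @export
make_timeseries_features <- function(windows, decimation_factor,
                                     n_taps = 31L) {
  f <- as.integer(decimation_factor)
  if (f < 1L) stop("decimation_factor must be >= 1", call. = FALSE)
  x <- windows$windows
  len <- ncol(x)
  p <- floor(len / f)
  if (p < 4L) {
    stop("decimation leaves fewer than 4 samples per window", call. = FALSE)
  }
  if (f > 1L) {
    h <- signal::fir1(n_taps - 1L, 0.8 / f)   # lowpass at 80% of the new Nyquist
    half <- (n_taps - 1L) %/% 2L
    # edge-replicate padding, centred convolution column-wise
    padded <- cbind(x[, rep(1L, half), drop = FALSE], x,
                    x[, rep(len, half), drop = FALSE])
    sm <- stats::filter(t(padded), h, method = "convolution", sides = 2)
    x <- t(sm)[, (half + 1L):(half + len), drop = FALSE]
  }
  idx <- seq(f, len, by = f)[seq_len(p)]
  structure(list(x = x[, idx, drop = FALSE], info = windows$info,
                 sampling_rate = windows$sampling_rate / f),
            class = "feature_set")
}

#' Subband power features: Welch power at 1-Hz resolution
#'
#' Each feature vector holds the Welch power estimates of the window at the
#' 1-Hz frequencies inside the band (1-s Hamming segments, 0.5-s overlap).
#'
#' @param windows A `window_set` (2-s windows).
#' @param band One-row band tibble (see [band_spec()]) or a band name.
#' @return A `feature_set` whose columns are named by frequency (Hz).
#' @export
make_subband_features <- function(windows, band) {
  if (is.character(band)) band <- band_spec(band)
  fs <- windows$sampling_rate
  if (band$high >= fs / 2) {
    stop("band high edge must be below Nyquist", call. = FALSE)
  }
  nperseg <- round(fs)                       # 1-s segments -> 1-Hz resolution
  ps <- welch_psd_matrix(windows$windows, fs, nperseg, max(1L, nperseg %/% 2L))
  sel <- ps$freq_hz >= band$low & ps$freq_hz <= band$high
  x <- ps$power[, sel, drop = FALSE]
  colnames(x) <- ps$freq_hz[sel]
  structure(list(x = x, info = windows$info, band = band$band),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d windows x %d features; %d signal / %d noise\n",
              nrow(x$x), ncol(x$x), sum(x$info$label == "signal"),
              sum(x$info$label == "noise")))
  invisible(x)
}
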