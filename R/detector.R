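#' Detector configuration
#'
#' @param wn Number of consecutive `"signal"`-classified windows required to
#'   register a detection (WN, >= 1).
#' @param refractory_s Dead time after a detection during which windows are
#'   ignored, seconds (default 2).
#' @param length_s,step_s Window geometry, seconds.
#' @return A `detector_config` list.
#' @export
detector_config <- function(wn, refractory_s = 2, length_s = 2, step_s = 0.1) {
  wn <- as.integer(wn)
  if (wn < 1L) stop("wn must be >= 1", call. = FALSE)
  if (refractory_s < 0) stop("refractory_s must be >= 0", call. = FALSE)
  structure(list(wn = wn, refractory_s = refractory_s,
                 length_s = length_s, step_s = step_s),
            class = "detector_config")
}

#' Run the consecutive-window brain switch
#'
#' Streams the per-window labels causally: a detection is emitted at the
#' trailing-edge time of the WN-th consecutive `"signal"` window. After a
#' detection the consecutive counter resets and windows falling inside the
#' refractory period are ignored.
#'
#' @param labels Per-window labels (`"signal"`/`"noise"`), in stream order.
#' @param times Trailing-edge time of each window, seconds.
#' @param config A [detector_config()].
#' @return A tibble with one row per detection (`time_s`).
#' @export
run_online_detector <- function(labels, times, config) {
  stopifnot(length(labels) == length(times))
  labels <- as.character(labels)
  wn <- config$wn
  det <- numeric(0)
  count <- 0L
  refract_until <- -Inf
  for (i in seq_along(labels)) {
    if (times[i] <= refract_until) next
    if (labels[i] == "signal") {
      count <- count + 1L
      if (count == wn) {
        det <- c(det, times[i])
        count <- 0L
        refract_until <- times[i] + config$refractory_s
      }
    } else {
      count <- 0L
    }
  }
  tibble::tibble(time_s = det)
}

#' Classify detections as true or false positives
#'
#' The detection latency DL is the detection time minus the nearest cue time.
#' A detection is a true positive when DL lies in the half-open interval
#' `(window[1], window[2]]` (default (-1, 1] s) and that cue has not already
#' been credited with an earlier true positive; every other detection is a
#' false positive.
#'
#' @param detections Tibble with a `time_s` column (from
#'   [run_online_detector()]).
#' @param cues Sorted cue times, seconds.
#' @param window Two-element latency window, seconds.
#' @return The detections tibble with `cue_s` (nearest cue), `dl_s`
#'   (latency) and `class` (`"TP"`/`"FP"`) added.
#' @export
classify_detections <- function(detections, cues, window = c(-1, 1)) {
  n <- nrow(detections)
  cls <- character(n)
  dl <- numeric(n)
  cue_of <- numeric(n)
  credited <- logical(length(cues))
  ord <- order(detections$time_s)
  for (i in ord) {
    t <- detections$time_s[i]
    j <- which.min(abs(cues - t))
    dl[i] <- t - cues[j]
    cue_of[i] <- cues[j]
    hit <- dl[i] > window[1] && dl[i] <= window[2] && !credited[j]
    if (hit) credited[j] <- TRUE
    cls[i] <- if (hit) "TP" else "FP"
  }
  out <- detections
  out$cue_s <- cue_of
  out$dl_s <- dl
  out$class <- factor(cls, levels = c("TP", "FP"))
  out
}

#' Score a window stream with the LPP-LDA (or LDA-only) pipeline
#'
#' @param features A `feature_set` for the stream, in causal order.
#' @param lda An `lda_model`.
#' @param lpp Optional `lpp_model` applied before the discriminant
#'   (time-series branch); `NULL` for the subband-power branch.
#' @return Factor of per-window labels (`"signal"`/`"noise"`).
#' @export
score_windows <- function(features, lda, lpp = NULL) {
  x <- features$x
  if (!is.null(lpp)) x <- project_lpp(lpp, x)
  predict(lda, x)
}
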