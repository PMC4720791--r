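#' Run-wise cross-validation plan
#'
#' Each run serves as the held-out test set exactly once, with the remaining
#' runs as the training set (three-fold for the standard three-run session).
#'
#' @param n_runs Number of runs (>= 2).
#' @return A tibble with columns `fold`, `train` (list of run indices),
#'   `test`.
#' @export
cv_plan <- function(n_runs = 3) {
  stopifnot(n_runs >= 2)
  tibble::tibble(
    fold = seq_len(n_runs),
    train = lapply(seq_len(n_runs), function(r) setdiff(seq_len(n_runs), r)),
    test = seq_len(n_runs)
  )
}

#' Calibrate the consecutive-window count under a false-positive bound
#'
#' Returns the smallest WN whose training false-positive rate does not exceed
#' `fp_limit` per minute. When no candidate qualifies, the largest WN is
#' returned with a warning (the strictest available detector).
#'
#' @param fp_per_min Training FP/min for each candidate, in `wn_values`
#'   order.
#' @param wn_values Candidate WN values (default `seq_along(fp_per_min)`).
#' @param fp_limit Bound in false positives per minute (default 8).
#' @return The selected WN (integer).
#' @examples
#' calibrate_wn(c(12, 9, 7, 3))  # -> 3
#' @export
calibrate_wn <- function(fp_per_min, wn_values = seq_along(fp_per_min),
                         fp_limit = 8) {
  if (!length(wn_values)) stop("wn_values must be non-empty", call. = FALSE)
  stopifnot(length(fp_per_min) == length(wn_values))
  ok <- which(fp_per_min <= fp_limit)
  if (length(ok)) {
    as.integer(wn_values[ok[1]])
  } else {
    warning("no WN meets the FP limit of ", fp_limit,
            "/min; using the largest candidate", call. = FALSE)
    as.integer(wn_values[length(wn_values)])
  }
}

#' Detection performance metrics
#'
#' @param events Classified detections (from [classify_detections()]).
#' @param cues Cue times of the evaluated stretch, seconds.
#' @param duration_s Total evaluated duration, seconds (> 0; the FP/min
#'   denominator, idle phases included).
#' @param wn WN used, recorded in the report.
#' @return A one-row tibble: `n_cues`, `n_tp`, `n_fp`, `tpr_pct`,
#'   `fp_per_min`, `dl_mean_ms`, `dl_sd_ms`, `wn`. Latency statistics are
#'   `NA` when there is no true positive.
#' @export
compute_metrics <- function(events, cues, duration_s, wn = NA_integer_) {
  if (length(cues) == 0) stop("no cues to evaluate against", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  n_tp <- sum(events$class == "TP")
  n_fp <- sum(events$class == "FP")
  dl_ms <- events$dl_s[events$class == "TP"] * 1000
  tibble::tibble(
    n_cues = length(cues),
    n_tp = n_tp,
    n_fp = n_fp,
    tpr_pct = 100 * n_tp / length(cues),
    fp_per_min = n_fp / (duration_s / 60),
    dl_mean_ms = if (n_tp) mean(dl_ms) else NA_real_,
    dl_sd_ms = if (n_tp > 1) stats::sd(dl_ms) else NA_real_,
    wn = as.integer(wn)
  )
}

# split a virtual channel into per-run stretches using run_start events
split_runs <- function(virtual) {
  fs <- virtual$sampling_rate
  starts <- virtual$events$onset_s[virtual$events$label == "run_start"]
  if (!length(starts)) starts <- 0
  ends <- c(starts[-1], length(virtual$samples) / fs)
  lapply(seq_along(starts), function(r) {
    idx <- (round(starts[r] * fs) + 1L):round(ends[r] * fs)
    list(samples = virtual$samples[idx], sampling_rate = fs,
         t0 = starts[r], duration_s = ends[r] - starts[r],
         cues = virtual$events$onset_s[virtual$events$label == "task" &
                                         virtual$events$run_index == r])
  })
}

#' Cross-validated brain-switch evaluation of one condition
#'
#' Runs the full pseudo-online protocol for one (band, technique) condition:
#' causal band-pass filtering, the large Laplacian, per-run sliding windows,
#' then for every fold the classifier (time-series LPP-LDA or subband-power
#' LDA) is fitted on the training runs, WN is calibrated on the training
#' runs under the FP bound, and the held-out run is streamed causally and
#' scored.
#'
#' @param recording An `eeg_recording` with `run_start` and `task` events.
#' @param band Band tibble or canonical band name.
#' @param technique `"timeseries"` (LPP then LDA on decimated samples) or
#'   `"subband"` (LDA on Welch subband power).
#' @param fp_limit Calibration bound, FP per minute (default 8).
#' @param wn_range Candidate WN values (default 1:10).
#' @param plan Cross-validation plan (default [cv_plan()] over the runs).
#' @param lpp_dim,lpp_k LPP output dimension and neighbourhood size.
#' @param decimation `"auto"` (sampling_rate / 20, ~40 samples per 2-s
#'   window) or an integer factor.
#' @param priors LDA prior mode (see [fit_lda()]).
#' @param refractory_s Detector refractory period, seconds.
#' @return A `cv_result`: list with `summary` (one-row pooled tibble
#'   including the condition), `folds` (per-fold metrics), `events`
#'   (classified detections with fold), `calibration` (per-fold FP/min by
#'   WN).
#' @export
crossvalidate_condition <- function(recording, band,
                                    technique = c("timeseries", "subband"),
                                    fp_limit = 8, wn_range = 1:10,
                                    plan = NULL, lpp_dim = 10, lpp_k = 5,
                                    decimation = "auto",
                                    priors = "empirical", refractory_s = 2) {
  technique <- match.arg(technique)
  if (is.character(band)) band <- band_spec(band)
  virt <- large_laplacian(bandpass_filter(recording, band, mode = "causal"))
  runs <- split_runs(virt)
  if (is.null(plan)) plan <- cv_plan(length(runs))
  if (length(runs) < max(unlist(plan$train), plan$test)) {
    stop("plan refers to more runs than the recording contains", call. = FALSE)
  }

  feats <- lapply(runs, function(rn) {
    ws <- sliding_windows(rn, cues = rn$cues, t0 = rn$t0)
    if (technique == "timeseries") {
      f <- if (identical(decimation, "auto")) {
        max(1L, round(rn$sampling_rate / 20))
      } else as.integer(decimation)
      make_timeseries_features(ws, f)
    } else {
      make_subband_features(ws, band)
    }
  })

  fold_out <- lapply(seq_len(nrow(plan)), function(i) {
    tr <- plan$train[[i]]
    te <- plan$test[i]
    xtr <- do.call(rbind, lapply(feats[tr], function(f) f$x))
    ytr <- unlist(lapply(feats[tr], function(f) as.character(f$info$label)))
    lpp <- NULL
    if (technique == "timeseries") {
      lpp <- fit_lpp(xtr, m = min(lpp_dim, ncol(xtr)), k = lpp_k)
      xfit <- project_lpp(lpp, xtr)
    } else {
      xfit <- xtr
    }
    lda <- fit_lda(xfit, ytr, priors = priors)

    stream_labels <- function(run_idx) {
      score_windows(feats[[run_idx]], lda, lpp)
    }
    train_labels <- lapply(tr, stream_labels)
    train_dur <- sum(vapply(runs[tr], function(r) r$duration_s, numeric(1)))
    fp_by_wn <- vapply(wn_range, function(wn) {
      cfg <- detector_config(wn, refractory_s = refractory_s)
      n_fp <- sum(vapply(seq_along(tr), function(j) {
        det <- run_online_detector(train_labels[[j]],
                                   feats[[tr[j]]]$info$time_s, cfg)
        sum(classify_detections(det, runs[[tr[j]]]$cues)$class == "FP")
      }, numeric(1)))
      n_fp / (train_dur / 60)
    }, numeric(1))
    wn <- calibrate_wn(fp_by_wn, wn_range, fp_limit)

    cfg <- detector_config(wn, refractory_s = refractory_s)
    det <- run_online_detector(stream_labels(te), feats[[te]]$info$time_s, cfg)
    ev <- classify_detections(det, runs[[te]]$cues)
    metrics <- compute_metrics(ev, runs[[te]]$cues, runs[[te]]$duration_s, wn)
    list(metrics = dplyr::mutate(metrics, fold = i, .before = 1),
         events = dplyr::mutate(ev, fold = i, .before = 1),
         calibration = tibble::tibble(fold = i, wn = as.integer(wn_range),
                                      fp_per_min = fp_by_wn),
         duration_s = runs[[te]]$duration_s)
  })

  folds <- dplyr::bind_rows(lapply(fold_out, `[[`, "metrics"))
  events <- dplyr::bind_rows(lapply(fold_out, `[[`, "events"))
  calibration <- dplyr::bind_rows(lapply(fold_out, `[[`, "calibration"))
  total_dur <- sum(vapply(fold_out, `[[`, numeric(1), "duration_s"))
  dl_ms <- events$dl_s[events$class == "TP"] * 1000
  summary <- tibble::tibble(
    task = attr(recording, "task_kind") %||% NA_character_,
    band = band$band,
    technique = technique,
    n_cues = sum(folds$n_cues),
    n_tp = sum(folds$n_tp),
    n_fp = sum(folds$n_fp),
    tpr_pct = 100 * sum(folds$n_tp) / sum(folds$n_cues),
    fp_per_min = sum(folds$n_fp) / (total_dur / 60),
    dl_mean_ms = if (length(dl_ms)) mean(dl_ms) else NA_real_,
    dl_sd_ms = if (length(dl_ms) > 1) stats::sd(dl_ms) else NA_real_,
    wn = as.integer(stats::median(folds$wn))
  )
  structure(list(summary = summary, folds = folds, events = events,
                 calibration = calibration),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> %s / %s / %s: TPR %.1f%% (%d/%d), FP %.2f/min, DL %s ms, WN %d\n",
              s$task, s$band, s$technique, s$tpr_pct, s$n_tp, s$n_cues,
              s$fp_per_min,
              if (is.na(s$dl_mean_ms)) "-" else
                sprintf("%.0f +/- %.0f", s$dl_mean_ms,
                        ifelse(is.na(s$dl_sd_ms), 0, s$dl_sd_ms)),
              s$wn))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' Glance at a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The pooled one-row summary tibble.
#' @export
glance.cv_result <- function(x, ...) x$summary

#' Full task-by-band-by-technique performance grid
#'
#' Evaluates every combination of the supplied recordings (one per task
#' kind), bands and techniques, mirroring the layout of the standard
#' comparison table (rows = band, columns = task x technique).
#'
#' @param recordings Named list of `eeg_recording`s, e.g.
#'   `list(ballistic = ..., repetitive = ...)`.
#' @param bands Character vector of canonical band names (default all six).
#' @param techniques Character vector among `"timeseries"`, `"subband"`.
#' @param ... Passed on to [crossvalidate_condition()].
#' @return A tibble of pooled condition summaries.
#' @export
run_condition_grid <- function(recordings,
                               bands = band_definitions()$band,
                               techniques = c("timeseries", "subband"),
                               ...) {
  grid <- tidyr::expand_grid(task = names(recordings), band = bands,
                             technique = techniques)
  purrr::pmap_dfr(grid, function(task, band, technique) {
    res <- crossvalidate_condition(recordings[[task]], band,
                                   technique = technique, ...)
    dplyr::mutate(res$summary, task = task)
  })
}
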