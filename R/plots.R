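#' Plot an MRCP significance profile
#'
#' Trial-mean amplitude difference from baseline per 0.1-s segment, with the
#' Holm-significant segments marked.
#'
#' @param object An `mrcp_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrcp_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$segment_center_s, .data$mean_diff_uv)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$significant, ], colour = "red", size = 1) +
    ggplot2::labs(x = "time relative to cue (s)",
                  y = "amplitude - baseline (µV)",
                  title = "MRCP significance profile",
                  subtitle = "red: segments Holm-significant vs the -3..-2 s reference") +
    ggplot2::theme_minimal()
}

#' Plot an ERD/ERS time-frequency map
#'
#' Relative SMR power as a heatmap (red = ERS, blue = ERD); when a bootstrap
#' mask is present, non-significant points are blanked.
#'
#' @param object A `tf_map` with `smr_pct` filled (see [erd_ers_percent()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_map <- function(object, ...) {
  if (is.null(object$smr_pct)) object <- erd_ers_percent(object)
  df <- tidy(object)
  if (!is.null(df$significant)) df$smr_pct[!df$significant] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = 100 * .data$smr_pct)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey95", name = "SMR %") +
    ggplot2::labs(x = "time relative to cue (s)", y = "frequency (Hz)",
                  title = "ERD/ERS map",
                  subtitle = "relative power vs the -3..-2 s reference") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated performance result
#'
#' Per-fold true positive rate and FP/min, with the pooled values overlaid.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$folds |>
    dplyr::select("fold", "tpr_pct", "fp_per_min") |>
    tidyr::pivot_longer(-"fold", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%s / %s / %s", object$summary$task,
                                  object$summary$band,
                                  object$summary$technique)) +
    ggplot2::theme_minimal()
}

#' Plot detections against the virtual-Cz trace
#'
#' @param virtual A `virtual_channel`.
#' @param events Classified detections (with `time_s`, `class`).
#' @param cues Cue times, seconds.
#' @param xlim Optional time range to display, seconds.
#' @return A ggplot.
#' @export
plot_detections <- function(virtual, events, cues, xlim = NULL) {
  t <- seq_along(virtual$samples) / virtual$sampling_rate
  df <- tibble::tibble(time_s = t, uv = virtual$samples)
  if (!is.null(xlim)) {
    df <- df[df$time_s >= xlim[1] & df$time_s <= xlim[2], ]
    events <- events[events$time_s >= xlim[1] & events$time_s <= xlim[2], ]
    cues <- cues[cues >= xlim[1] & cues <= xlim[2]]
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$uv)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = cues, linetype = 3) +
    ggplot2::geom_point(data = events,
                        ggplot2::aes(.data$time_s, 0, colour = .data$class),
                        shape = 8, size = 3, inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = c(TP = "darkgreen", FP = "red")) +
    ggplot2::labs(x = "time (s)", y = "virtual Cz (µV)",
                  title = "Brain-switch detections",
                  subtitle = "dotted lines: task cues") +
    ggplot2::theme_minimal()
}
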