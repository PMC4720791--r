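#' SMR band modulation specification
#'
#' Describes one injected sensorimotor rhythm: a band-limited carrier whose
#' power is modulated around each task cue by an event-related
#' desynchronization (ERD, a power dip) and/or an event-related
#' synchronization (ERS, a power rise such as the post-movement beta rebound).
#'
#' @param name Band label.
#' @param center_hz,bandwidth_hz Carrier centre frequency and bandwidth (Hz).
#' @param amplitude_uv Baseline carrier RMS amplitude at the virtual-Cz level
#'   (microvolts).
#' @param erd_depth Fractional power drop during ERD, in `[0, 1]`.
#' @param ers_gain Multiplicative power gain at the ERS peak, `>= 1`.
#' @param erd_onset_s,erd_duration_s ERD window relative to the cue (seconds).
#' @param ers_onset_s,ers_duration_s ERS window relative to the cue (seconds),
#'   for the ballistic task; the repetitive task delays the ERS (see
#'   [smr_modulation_profile()]).
#' @return A one-row tibble.
#' @export
smr_band <- function(name, center_hz, bandwidth_hz, amplitude_uv = 3,
                     erd_depth = 0, ers_gain = 1,
                     erd_onset_s = -0.5, erd_duration_s = 2,
                     ers_onset_s = 0.8, ers_duration_s = 1.5) {
  stopifnot(erd_depth >= 0, erd_depth <= 1, ers_gain >= 1,
            erd_duration_s > 0, ers_duration_s > 0,
            center_hz > 0, bandwidth_hz > 0, amplitude_uv >= 0)
  tibble::tibble(
    name = name, center_hz = center_hz, bandwidth_hz = bandwidth_hz,
    amplitude_uv = amplitude_uv, erd_depth = erd_depth, ers_gain = ers_gain,
    erd_onset_s = erd_onset_s, erd_duration_s = erd_duration_s,
    ers_onset_s = ers_onset_s, ers_duration_s = ers_duration_s
  )
}

#' Default SMR band set: alpha ERD and a beta rebound
#'
#' An alpha-band rhythm with a marked ERD around movement imagination and a
#' beta-band rhythm with a post-onset ERS (beta rebound), the two signatures
#' most consistently reported over the foot area of sensorimotor cortex.
#'
#' @return A tibble of [smr_band()] rows.
#' @export
default_smr_bands <- function() {
  dplyr::bind_rows(
    smr_band("alpha", center_hz = 10.5, bandwidth_hz = 5, amplitude_uv = 4,
             erd_depth = 0.5, ers_gain = 1,
             erd_onset_s = -0.5, erd_duration_s = 2.5),
    smr_band("beta", center_hz = 21, bandwidth_hz = 8, amplitude_uv = 3,
             erd_depth = 0.3, ers_gain = 1.8,
             erd_onset_s = -0.5, erd_duration_s = 1.2,
             ers_onset_s = 0.8, ers_duration_s = 1.5)
  )
}

#' Default nine-channel 10-20 spatial profile
#'
#' Injection gain of the simulated cortical sources at each electrode:
#' maximal at Cz (over the foot representation) and attenuated at the eight
#' surrounding sites.
#'
#' @return Named numeric vector of per-channel gains.
#' @export
default_spatial_profile <- function() {
  c(Cz = 1, Fz = 0.3, F3 = 0.3, F4 = 0.3, C3 = 0.3, C4 = 0.3,
    P3 = 0.3, P4 = 0.3, Pz = 0.3)
}

#' Simulation configuration
#'
#' Bundles every parameter of a simulated motor-imagery EEG session: the trial
#' phase structure (idle, focus, preparation, task), the run/trial counts, the
#' injected MRCP and SMR content, the background noise, and the RNG seed.
#'
#' @param task_kind `"ballistic"` (one brisk imagined dorsiflexion at task
#'   onset) or `"repetitive"` (~1 Hz repeated imagery across the 4-s task).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Nine 10-20 channel names, Cz plus its eight
#'   neighbours.
#' @param n_runs Number of runs of this task kind.
#' @param trials_per_run Trials per run.
#' @param phase_durations Named durations in seconds of the idle, focus,
#'   preparation and task phases.
#' @param mrcp_amplitude Peak MRCP negativity in microvolts, expressed at the
#'   virtual-Cz (post-Laplacian) level.
#' @param smr_bands Tibble of [smr_band()] rows (possibly empty).
#' @param noise List with elements `pink_uv`, `white_uv` (per-channel RMS
#'   amplitudes) and `mixing` (fraction of noise power shared across
#'   channels, in `[0, 1)`).
#' @param spatial_profile Named per-channel injection gains; must cover
#'   `channel_labels` and be maximal at the centre channel.
#' @param seed Integer RNG seed; the session is a pure function of the
#'   configuration including this seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(task_kind = c("ballistic", "repetitive"),
                       sampling_rate = 1200,
                       channel_labels = names(default_spatial_profile()),
                       n_runs = 3,
                       trials_per_run = 20,
                       phase_durations = c(idle = 5, focus = 2,
                                           preparation = 3, task = 4),
                       mrcp_amplitude = 10,
                       smr_bands = default_smr_bands(),
                       noise = list(pink_uv = 8, white_uv = 2, mixing = 0.6),
                       spatial_profile = default_spatial_profile(),
                       seed = 1L) {
  task_kind <- match.arg(task_kind)
  cfg <- list(
    task_kind = task_kind, sampling_rate = sampling_rate,
    channel_labels = channel_labels, n_runs = n_runs,
    trials_per_run = trials_per_run, phase_durations = phase_durations,
    mrcp_amplitude = mrcp_amplitude, smr_bands = smr_bands, noise = noise,
    spatial_profile = spatial_profile, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!(is.numeric(cfg$sampling_rate) && cfg$sampling_rate > 0)) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  if (length(cfg$channel_labels) != 9L) {
    stop("channel_labels must name exactly 9 channels (Cz + 8 neighbours)",
         call. = FALSE)
  }
  if (!all(c("idle", "focus", "preparation", "task") %in%
           names(cfg$phase_durations)) || any(cfg$phase_durations <= 0)) {
    stop("phase_durations must give positive idle/focus/preparation/task",
         call. = FALSE)
  }
  if (cfg$n_runs < 1 || cfg$trials_per_run < 1) {
    stop("n_runs and trials_per_run must be >= 1", call. = FALSE)
  }
  if (cfg$mrcp_amplitude < 0) {
    stop("mrcp_amplitude must be non-negative", call. = FALSE)
  }
  if (nrow(cfg$smr_bands) > 0) {
    stopifnot(all(cfg$smr_bands$erd_depth >= 0 & cfg$smr_bands$erd_depth <= 1),
              all(cfg$smr_bands$ers_gain >= 1))
  }
  if (!all(is.finite(cfg$spatial_profile)) ||
      !all(cfg$channel_labels %in% names(cfg$spatial_profile))) {
    stop("spatial_profile must give a finite gain for every channel",
         call. = FALSE)
  }
  nz <- cfg$noise
  if (nz$pink_uv < 0 || nz$white_uv < 0 || nz$mixing < 0 || nz$mixing >= 1) {
    stop("noise amplitudes must be >= 0 and mixing in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

# raised-cosine ramp from 0 at a to 1 at b, clamped outside
rc_ramp <- function(t, a, b) {
  u <- pmin(pmax((t - a) / (b - a), 0), 1)
  (1 - cos(pi * u)) / 2
}

# raised-cosine bump: 0 at both ends, 1 at the midpoint of [a, b]
rc_bump <- function(t, a, b) {
  u <- (t - a) / (b - a)
  ifelse(u > 0 & u < 1, (1 - cos(2 * pi * u)) / 2, 0)
}

#' Movement-related cortical potential template
#'
#' The canonical single-trial MRCP waveform on the epoch axis `t` in
#' `[-3, 6]` s relative to the task cue. Both task kinds share the pre-onset
#' negative limb (a smooth fall beginning ~2 s before the cue, reaching the
#' peak negativity `-amplitude` at `t = 0`). The ballistic template rebounds
#' through a small positive overshoot and is back at baseline by ~2 s; the
#' repetitive template instead relaxes onto a sustained negative plateau that
#' persists through the 4-s task phase before decaying to baseline by 6 s.
#'
#' @param task_kind `"ballistic"` or `"repetitive"`.
#' @param amplitude Peak negativity in microvolts (non-negative).
#' @param sampling_rate Sampling rate in Hz.
#' @return A tibble with columns `time_s` and `value_uv`.
#' @examples
#' tpl <- mrcp_template("ballistic", 10, 200)
#' tpl$time_s[which.min(tpl$value_uv)]  # peak negativity at the cue
#' @export
mrcp_template <- function(task_kind = c("ballistic", "repetitive"),
                          amplitude, sampling_rate) {
  task_kind <- match.arg(task_kind)
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("amplitude must be non-negative", call. = FALSE)
  }
  t <- seq(-3, 6, by = 1 / sampling_rate)
  a <- amplitude
  fall <- -a * rc_ramp(t, -2, 0) * (t <= 0)
  if (task_kind == "ballistic") {
    # rebound to +0.15 a by 1 s, then decay to 0 by 2 s
    reb1 <- (-a + 1.15 * a * rc_ramp(t, 0, 1)) * (t > 0 & t <= 1)
    reb2 <- 0.15 * a * (1 - rc_ramp(t, 1, 2)) * (t > 1 & t < 2)
    v <- fall + reb1 + reb2
  } else {
    # relax to a -0.6 a plateau held through the task, decay after 4 s
    rel <- (-a + 0.4 * a * rc_ramp(t, 0, 1)) * (t > 0 & t <= 1)
    plat <- -0.6 * a * (t > 1 & t <= 4)
    dec <- -0.6 * a * (1 - rc_ramp(t, 4, 6)) * (t > 4)
    v <- fall + rel + plat + dec
  }
  tibble::tibble(time_s = t, value_uv = v)
}

#' Time-varying SMR power-gain envelope
#'
#' Power gain of one SMR carrier across the epoch `t` in `[-3, 6]` s: 1 at
#' baseline, dipping to `1 - erd_depth` during the ERD and rising to
#' `ers_gain` at the ERS peak. For the repetitive task the ERD is stretched to
#' cover the whole 4-s task phase and the ERS (beta rebound) is delayed by
#' `repetitive_ers_delay_s`, reproducing the later rebound seen with
#' sustained imagery.
#'
#' @param task_kind `"ballistic"` or `"repetitive"`.
#' @param band One [smr_band()] row.
#' @param sampling_rate Sampling rate in Hz.
#' @param repetitive_ers_delay_s Extra ERS onset delay for the repetitive
#'   task (seconds, default 2).
#' @return A tibble with columns `time_s` and `gain` (power gain, >= 0).
#' @export
smr_modulation_profile <- function(task_kind = c("ballistic", "repetitive"),
                                   band, sampling_rate,
                                   repetitive_ers_delay_s = 2) {
  task_kind <- match.arg(task_kind)
  stopifnot(nrow(band) == 1L)
  t <- seq(-3, 6, by = 1 / sampling_rate)
  erd_a <- band$erd_onset_s
  erd_b <- erd_a + band$erd_duration_s
  ers_a <- band$ers_onset_s
  if (task_kind == "repetitive") {
    erd_b <- max(erd_b, 4)                 # ERD sustained across the task
    ers_a <- ers_a + repetitive_ers_delay_s
  }
  ers_b <- ers_a + band$ers_duration_s
  gain <- 1 - band$erd_depth * rc_bump(t, erd_a, erd_b) +
    (band$ers_gain - 1) * rc_bump(t, ers_a, ers_b)
  tibble::tibble(time_s = t, gain = pmax(gain, 0))
}

# unit-RMS 1/f ("pink") noise via spectral shaping of white noise;
# spectrum flattened below f_floor to keep the variance finite
pink_noise <- function(n, sampling_rate, f_floor = 0.1) {
  w <- stats::rnorm(n)
  f <- seq(0, sampling_rate / 2, length.out = floor(n / 2) + 1)
  shape_half <- 1 / sqrt(pmax(f, f_floor))
  # full Hermitian-symmetric gain vector matching fft() bin order
  shape <- c(shape_half, rev(shape_half[2:(n - length(shape_half) + 1)]))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Correlated EEG background noise
#'
#' Sum of 1/f-spectrum ("pink") and white noise at the configured per-channel
#' RMS amplitudes. A fraction `mixing` of each component's power is a source
#' common to all channels (volume-conducted background), the rest is
#' channel-independent.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param n_channels Number of channels.
#' @param noise_params List with `pink_uv`, `white_uv`, `mixing`.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [generate_session()]).
#' @return A numeric matrix `[n_channels x samples]` in microvolts.
#' @export
background_noise <- function(duration_s, n_channels, noise_params,
                             sampling_rate, seed = NULL) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  draw <- function() {
    n <- round(duration_s * sampling_rate)
    out <- matrix(0, n_channels, n)
    p <- noise_params$pink_uv
    w <- noise_params$white_uv
    m <- noise_params$mixing
    if (p > 0) {
      common <- pink_noise(n, sampling_rate)
      for (ch in seq_len(n_channels)) {
        out[ch, ] <- out[ch, ] + p * (sqrt(m) * common +
                                        sqrt(1 - m) * pink_noise(n, sampling_rate))
      }
    }
    if (w > 0) {
      common <- stats::rnorm(n)
      out <- out + w * (sqrt(m) * matrix(common, n_channels, n, byrow = TRUE) +
                          sqrt(1 - m) * matrix(stats::rnorm(n_channels * n),
                                               n_channels, n))
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic motor-imagery EEG session
#'
#' Builds a seeded multi-run recording with the four-phase trial structure
#' (idle, focus, preparation, task), one cue event at each task onset, and
#' run-boundary events. The MRCP template and the SMR carriers (band-limited
#' noise whose amplitude follows the square root of the power-gain envelope)
#' are injected through the spatial profile on top of correlated pink + white
#' background noise. Source amplitudes are expressed at the virtual-Cz level:
#' with zero noise and no SMR bands, epoching the large-Laplacian output
#' recovers the MRCP template exactly.
#'
#' @param config A [sim_config()].
#' @return An `eeg_recording`: list with `samples` (channels x time matrix,
#'   microvolts), `channel_labels`, `sampling_rate`, and an `events` tibble
#'   (`onset_s`, `label`, `run_index`) holding one `"task"` cue per trial and
#'   one `"run_start"` per run.
#' @examples
#' rec <- generate_session(sim_config(n_runs = 1, trials_per_run = 2,
#'                                    sampling_rate = 120, seed = 7))
#' rec$events
#' @export
generate_session <- function(config) {
  validate_sim_config(config)
  fs <- config$sampling_rate
  trial_dur <- sum(config$phase_durations)
  run_dur <- config$trials_per_run * trial_dur
  # one trailing idle phase so the last trial has full post-cue context
  total_dur <- config$n_runs * run_dur +
    unname(config$phase_durations["idle"])
  n <- round(total_dur * fs)
  cue_offset <- sum(config$phase_durations[c("idle", "focus", "preparation")])

  runs <- seq_len(config$n_runs) - 1L
  cues <- as.vector(vapply(runs, function(r) {
    r * run_dur + (seq_len(config$trials_per_run) - 1L) * trial_dur + cue_offset
  }, numeric(config$trials_per_run)))

  gains <- config$spatial_profile[config$channel_labels]
  center <- config$channel_labels[1]
  lap_gain <- gains[center] - mean(gains[config$channel_labels != center])
  if (abs(lap_gain) < 1e-12) {
    stop("spatial_profile is invisible to the Laplacian filter", call. = FALSE)
  }

  samples <- withr::with_seed(config$seed, {
    out <- background_noise(total_dur, length(config$channel_labels),
                            config$noise, fs)
    source <- numeric(n)
    tpl <- mrcp_template(config$task_kind, config$mrcp_amplitude, fs)$value_uv
    cue_samp <- round(cues * fs) + 1L
    for (cs in cue_samp) {
      idx <- (cs - 3L * fs):(cs + 6L * fs)
      keep <- idx >= 1L & idx <= n
      source[idx[keep]] <- source[idx[keep]] + tpl[keep]
    }
    if (nrow(config$smr_bands) > 0) {
      for (b in seq_len(nrow(config$smr_bands))) {
        band <- config$smr_bands[b, ]
        lo <- (band$center_hz - band$bandwidth_hz / 2) / (fs / 2)
        hi <- (band$center_hz + band$bandwidth_hz / 2) / (fs / 2)
        bf <- signal::butter(4, c(lo, hi), type = "pass")
        carrier <- signal::filter(bf, stats::rnorm(n))
        carrier <- as.numeric(carrier) / stats::sd(carrier)
        env <- rep(1, n)
        prof <- smr_modulation_profile(config$task_kind, band, fs)$gain
        for (cs in cue_samp) {
          idx <- (cs - 3L * fs):(cs + 6L * fs)
          keep <- idx >= 1L & idx <= n
          env[idx[keep]] <- prof[keep]
        }
        source <- source + band$amplitude_uv * carrier * sqrt(env)
      }
    }
    out + outer(unname(gains) / lap_gain, source)
  })

  events <- dplyr::bind_rows(
    tibble::tibble(onset_s = runs * run_dur, label = "run_start",
                   run_index = runs + 1L),
    tibble::tibble(onset_s = cues, label = "task",
                   run_index = rep(runs + 1L, each = config$trials_per_run))
  ) |> dplyr::arrange(.data$onset_s, .data$label)

  rec <- new_eeg_recording(samples, config$channel_labels, fs, events)
  attr(rec, "task_kind") <- config$task_kind
  rec
}

#' Construct an EEG recording object
#'
#' @param samples Numeric matrix `[channels x time]` in microvolts.
#' @param channel_labels Character vector, one label per row of `samples`.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Tibble with columns `onset_s`, `label` and optionally
#'   `run_index`; onsets must lie inside the recording and cue onsets must be
#'   strictly increasing.
#' @return An `eeg_recording`.
#' @export
new_eeg_recording <- function(samples, channel_labels, sampling_rate, events) {
  stopifnot(is.matrix(samples), nrow(samples) == length(channel_labels))
  events <- tibble::as_tibble(events)
  dur <- ncol(samples) / sampling_rate
  if (any(events$onset_s < 0 | events$onset_s > dur)) {
    stop("event onsets must lie within the recording", call. = FALSE)
  }
  cue <- events$onset_s[events$label == "task"]
  if (length(cue) > 1 && any(diff(cue) <= 0)) {
    stop("cue onsets must be strictly increasing", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, channel_labels = channel_labels,
                 sampling_rate = sampling_rate, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  cat(sprintf("  channels: %s\n", paste(x$channel_labels, collapse = ", ")))
  cat(sprintf("  events: %d (%d task cues)\n", nrow(x$events),
              sum(x$events$label == "task")))
  invisible(x)
}

#' Cue (task-onset) times of a recording
#'
#' @param recording An `eeg_recording`.
#' @param run Optional run index to restrict to.
#' @return Numeric vector of cue onset times in seconds.
#' @export
cue_times <- function(recording, run = NULL) {
  ev <- recording$events[recording$events$label == "task", ]
  if (!is.null(run)) ev <- ev[ev$run_index %in% run, ]
  ev$onset_s
}
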