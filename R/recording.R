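#' Specification of one simulated nerve fiber (unit)
#'
#' @param unit_id Unique identifier (character or integer).
#' @param channel_id Channel (1-12, [tflife_channels()] layout) on which the
#'   unit's spikes appear. Each intrafascicular site sees its own small set
#'   of fibers, so units belong to exactly one channel.
#' @param shape [waveform_shape()] rendered for every spike of this unit.
#' @param baseline_rate_hz Rate outside cued epochs and during classes the
#'   unit is not modulated by (>= 0).
#' @param class_rate_profiles Named list mapping class labels to
#'   [rate_profile()] objects over normalized epoch time. Classes absent
#'   from the list fall back to the baseline rate.
#' @param refractory_ms Absolute refractory period (> 0), default 1 ms.
#' @return Object of class `eng_unit_spec`.
#' @export
unit_spec <- function(unit_id, channel_id, shape, baseline_rate_hz,
                      class_rate_profiles = list(), refractory_ms = 1) {
  if (baseline_rate_hz < 0) stop_invalid("baseline_rate_hz must be >= 0")
  if (refractory_ms <= 0) stop_invalid("refractory_ms must be positive")
  if (!inherits(shape, "eng_waveform_shape"))
    stop_invalid("shape must be an eng_waveform_shape")
  bad <- setdiff(names(class_rate_profiles), grip_classes())
  if (length(bad) > 0)
    stop_invalid("unknown class label(s): ", paste(bad, collapse = ", "))
  structure(
    list(unit_id = as.character(unit_id), channel_id = as.integer(channel_id),
         shape = shape, baseline_rate_hz = baseline_rate_hz,
         class_rate_profiles = class_rate_profiles,
         refractory_ms = refractory_ms),
    class = "eng_unit_spec"
  )
}

#' Band-limited Gaussian noise specification
#'
#' White Gaussian noise shaped by a zero-phase 4th-order Butterworth
#' band-pass, emulating the 100 Hz - 10 kHz acquisition band of the
#' recording chain. Either a fixed standard deviation or a target SNR may be
#' given; with a target, the noise level is calibrated per channel (see
#' [render_recording()]).
#'
#' @param sigma_uV Standard deviation of the white noise before filtering,
#'   in microvolts; either a scalar or a named vector with one entry per
#'   channel id. Ignored when `target_snr_db` is given.
#' @param bandpass_hz Length-2 vector `(low, high)`, 0 < low < high.
#' @param target_snr_db Optional per-channel SNR target in dB under the
#'   spike-window RMS definition of [estimate_snr()].
#' @return Object of class `eng_noise_spec`.
#' @export
noise_spec <- function(sigma_uV = 0, bandpass_hz = c(100, 10000),
                       target_snr_db = NULL) {
  if (is.null(target_snr_db) && any(sigma_uV < 0))
    stop_invalid("sigma_uV must be nonnegative")
  if (length(bandpass_hz) != 2 || bandpass_hz[1] <= 0 ||
      bandpass_hz[2] <= bandpass_hz[1])
    stop_invalid("bandpass_hz must satisfy 0 < low < high")
  structure(list(sigma_uV = sigma_uV, bandpass_hz = bandpass_hz,
                 target_snr_db = target_snr_db),
            class = "eng_noise_spec")
}

#' Randomized cued-epoch plan
#'
#' Epochs are fixed-width, half-open `[start, end)` intervals separated by a
#' constant gap; the class sequence is a seeded random shuffle of the
#' requested class counts, emulating the random presentation of task cues.
#'
#' @param classes Class labels to cue; subset of [grip_classes()].
#' @param epochs_per_class Number of epochs of each class.
#' @param epoch_s Epoch duration in seconds (> 0).
#' @param gap_s Gap between consecutive epochs (>= 0).
#' @param lead_in_s Silence before the first epoch.
#' @param seed Seed for the class-order shuffle.
#' @return Object of class `eng_epoch_plan`.
#' @export
epoch_plan <- function(classes = grip_classes(), epochs_per_class = 20,
                       epoch_s = 3, gap_s = 0.5, lead_in_s = 0.5, seed = 1) {
  if (!all(classes %in% grip_classes()))
    stop_invalid("classes must be a subset of grip_classes()")
  if (epoch_s <= 0) stop_invalid("epoch_s must be positive")
  if (gap_s < 0) stop_invalid("gap_s must be nonnegative")
  structure(list(classes = classes, epochs_per_class = epochs_per_class,
                 epoch_s = epoch_s, gap_s = gap_s, lead_in_s = lead_in_s,
                 seed = as.integer(seed)),
            class = "eng_epoch_plan")
}

#' Realize an epoch plan as a table of labeled windows
#'
#' @param plan An [epoch_plan()].
#' @return data.frame with columns `epoch_id`, `start_s`, `end_s`, `class`.
#' @export
build_epochs <- function(plan) {
  if (!inherits(plan, "eng_epoch_plan")) stop_invalid("plan must be an eng_epoch_plan")
  labels <- rep(plan$classes, each = plan$epochs_per_class)
  local_seed(plan$seed)
  labels <- sample(labels)
  n <- length(labels)
  starts <- plan$lead_in_s + (seq_len(n) - 1) * (plan$epoch_s + plan$gap_s)
  data.frame(epoch_id = seq_len(n), start_s = starts,
             end_s = starts + plan$epoch_s, class = labels,
             stringsAsFactors = FALSE)
}

# total recording duration implied by an epoch table
epochs_duration <- function(epochs, tail_s = 0.5) {
  max(epochs$end_s) + tail_s
}

# rate of a unit as a function of absolute time, given the epoch table
unit_rate_fn <- function(unit, epochs) {
  force(unit); force(epochs)
  function(t) {
    r <- rep(unit$baseline_rate_hz, length(t))
    for (i in seq_len(nrow(epochs))) {
      cls <- epochs$class[i]
      prof <- unit$class_rate_profiles[[cls]]
      if (is.null(prof)) next
      inside <- t >= epochs$start_s[i] & t < epochs$end_s[i]
      if (!any(inside)) next
      pct <- (t[inside] - epochs$start_s[i]) /
        (epochs$end_s[i] - epochs$start_s[i]) * 100
      r[inside] <- eval_rate_profile(prof, pct)
    }
    r
  }
}

unit_rate_max <- function(unit) {
  profs <- unit$class_rate_profiles
  max(unit$baseline_rate_hz,
      if (length(profs)) max(vapply(profs, rate_profile_max, numeric(1))) else 0)
}

# zero-phase 4th-order Butterworth band-pass
bandpass_filter <- function(x, bandpass_hz, fs) {
  bf <- signal::butter(4, bandpass_hz / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Render a multi-channel recording with ground truth
#'
#' Superimposes each unit's rendered waveform at spike times drawn from its
#' class-modulated inhomogeneous Poisson process, then adds band-limited
#' Gaussian noise. The same configuration and seed give bit-identical
#' output. When the noise spec carries `target_snr_db`, the noise level on
#' each channel with units is calibrated so that [estimate_snr()] applied to
#' the noisy trace with the true spike times has that expectation (for
#' targets above 0 dB; lower targets are calibrated against the clean-signal
#' spike RMS, since the windowed-RMS estimator saturates near 0 dB).
#'
#' @param units List of [unit_spec()] objects; channels must be within
#'   `channels`.
#' @param epochs Epoch table from [build_epochs()] (or any data.frame with
#'   `start_s`, `end_s`, `class`).
#' @param noise [noise_spec()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed controlling spike times and noise.
#' @param channels Integer vector of channel ids to render.
#' @param day_id Identifier stored with the recording.
#' @param duration_s Recording length; defaults to the end of the last epoch
#'   plus half a second.
#' @return List with elements `recording` (class `eng_recording`: `data` a
#'   channels x samples matrix in microvolts, `fs`, `channels`, `day_id`)
#'   and `truth` (class `eng_ground_truth`: `spikes` data.frame with
#'   `unit_id`, `channel_id`, `time_s`; `epochs`; `units`; `day_id`).
#' @export
render_recording <- function(units, epochs, noise, fs = 25000, seed = 1,
                             channels = NULL, day_id = "day1",
                             duration_s = NULL) {
  if (is.null(channels)) {
    channels <- if (length(units) > 0)
      sort(unique(vapply(units, function(u) u$channel_id, integer(1))))
    else 1L
  }
  unit_channels <- vapply(units, function(u) u$channel_id, integer(1))
  if (length(units) > 0 && !all(unit_channels %in% channels))
    stop_invalid("every unit channel must be in the declared channel set")
  if (!all(channels %in% tflife_channels()$channel_id))
    stop_invalid("channels must be within the 12-channel tfLIFE layout")
  if (is.null(duration_s)) duration_s <- epochs_duration(epochs)
  n <- round(duration_s * fs)

  # sub-seeds are derived from the identities of units and channels, not
  # from their positions, so rendering units jointly or separately (with
  # the same recording seed) produces identical spike trains and noise:
  # superposition is exact
  local_seed(seed)
  base_seeds <- sample.int(2^30, 2)

  clean <- matrix(0, nrow = length(channels), ncol = n)
  rownames(clean) <- as.character(channels)
  spike_tabs <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    times <- sample_spike_train(unit_rate_fn(u, epochs), duration_s,
                                u$refractory_ms,
                                seed = derive_seed(base_seeds[1], u$unit_id),
                                lambda_max = unit_rate_max(u))
    if (length(times) > 0) {
      w <- render_waveform(u$shape)
      peak_at <- which.max(abs(w)) - 1L
      onsets <- as.integer(round(times * fs)) - peak_at
      row <- match(u$channel_id, channels)
      sig <- clean[row, ]
      add_at(sig, w, onsets)   # in-place on the copied row
      clean[row, ] <- sig
      spike_tabs[[length(spike_tabs) + 1]] <- data.frame(
        unit_id = u$unit_id, channel_id = u$channel_id, time_s = times,
        stringsAsFactors = FALSE)
    }
  }
  spikes <- if (length(spike_tabs) > 0) do.call(rbind, spike_tabs)
  else data.frame(unit_id = character(), channel_id = integer(),
                  time_s = numeric(), stringsAsFactors = FALSE)
  spikes <- spikes[order(spikes$time_s), , drop = FALSE]
  rownames(spikes) <- NULL

  data <- clean
  noise_sigmas <- numeric(length(channels))
  names(noise_sigmas) <- as.character(channels)
  for (j in seq_along(channels)) {
    sig_noise <- noise_sigma_for_channel(
      noise, clean[j, ], spikes[spikes$channel_id == channels[j], "time_s"],
      fs, seed = derive_seed(base_seeds[2], channels[j]),
      channel_id = channels[j])
    noise_sigmas[j] <- sig_noise$sigma
    if (sig_noise$sigma > 0) data[j, ] <- clean[j, ] + sig_noise$noise
  }

  recording <- structure(
    list(data = data, fs = fs, channels = channels, day_id = day_id,
         units_uV = TRUE, seed = seed, noise_sigma_uV = noise_sigmas),
    class = "eng_recording")
  truth <- structure(
    list(spikes = spikes, epochs = epochs, units = units, day_id = day_id),
    class = "eng_ground_truth")
  list(recording = recording, truth = truth)
}

# draw band-limited noise for one channel, calibrated if a target SNR is set;
# returns list(sigma, noise) where noise is already scaled
noise_sigma_for_channel <- function(noise, clean, spike_times_s, fs, seed,
                                    channel_id = NULL) {
  local_seed(seed)
  raw <- rnorm(length(clean))
  if (is.null(noise$target_snr_db)) {
    sig <- noise$sigma_uV
    if (length(sig) > 1 || !is.null(names(sig))) {
      key <- as.character(channel_id)
      if (!key %in% names(sig))
        stop_invalid("no noise sigma given for channel ", key)
      sig <- sig[[key]]
    }
    if (sig == 0)
      return(list(sigma = 0, noise = NULL))
    shaped <- bandpass_filter(raw * sig, noise$bandpass_hz, fs)
    return(list(sigma = sig, noise = shaped))
  }
  shaped <- bandpass_filter(raw, noise$bandpass_hz, fs)
  if (length(spike_times_s) == 0) {
    # no units on this channel: unit-variance input noise
    return(list(sigma = 1, noise = shaped))
  }
  idx <- spike_window_index(spike_times_s, fs, length(clean), window_ms = 1)
  s_rms <- sqrt(mean(clean[idx]^2))
  n0_rms <- sqrt(mean(shaped^2))
  r <- 10^(noise$target_snr_db / 20)
  # solve 20*log10(sqrt(S^2 + sigma^2 N0^2) / (sigma N0)) = target when the
  # target is meaningfully above 0 dB; otherwise fall back to the clean
  # signal-to-noise ratio definition
  sigma <- if (noise$target_snr_db > 0.5) {
    s_rms / (n0_rms * sqrt(r^2 - 1))
  } else {
    s_rms / (n0_rms * r)
  }
  list(sigma = sigma, noise = shaped * sigma)
}

# deterministic sub-seed from a base seed and an identifier string
derive_seed <- function(base, id) {
  codes <- utf8ToInt(as.character(id))
  h <- sum(codes * seq_along(codes)) %% 65536
  (base + h * 1009) %% 2^30
}

# indices (1-based) of samples within +/- window_ms of any spike time
spike_window_index <- function(spike_times_s, fs, n, window_ms = 1) {
  if (length(spike_times_s) == 0) return(integer())
  half <- round(window_ms / 1000 * fs)
  centers <- round(spike_times_s * fs) + 1
  idx <- unlist(lapply(centers, function(c0) {
    seq(max(1, c0 - half), min(n, c0 + half))
  }))
  sort(unique(idx))
}

#' @export
print.eng_recording <- function(x, ...) {
  cat(sprintf("<eng_recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$day_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
print.eng_ground_truth <- function(x, ...) {
  cat(sprintf("<eng_ground_truth> %s: %d spikes from %d unit(s), %d epochs\n",
              x$day_id, nrow(x$spikes), length(x$units), nrow(x$epochs)))
  invisible(x)
}
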