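#' Configuration for the two-day study fixture
#'
#' The fixture emulates the study's recording conditions: a handful of
#' informative tfLIFE channels (one per electrode group by default), two to
#' three units per informative channel with well-separated waveforms,
#' class-specific firing-rate modulation including a double-peaked palmar
#' profile, band-limited noise calibrated to a target SNR, and a randomized
#' cued-epoch sequence for three movements plus rest, repeated on two days
#' with optional day-to-day drift.
#'
#' @param fs Sampling rate in Hz.
#' @param epochs_per_class Epochs of each class per day.
#' @param epoch_s Epoch duration in seconds.
#' @param gap_s Gap between epochs in seconds.
#' @param target_snr_db Configured SNR on informative channels, in dB.
#' @param informative_channels Channels that carry units (default one site
#'   on each of M1, M2, U).
#' @param noise_channels Extra channels carrying only noise.
#' @param amp_drift Relative day-2 waveform amplitude change (0.2 = +20%).
#' @param rate_drift Relative day-2 firing-rate change.
#' @param baseline_hz Baseline firing rate of every unit in spikes/s.
#' @param rate_scale Multiplier on all bump amplitudes; lowering it makes
#'   the class-conditional rate patterns overlap more (harder problem).
#' @param seed Master seed; per-day seeds are derived from it.
#' @return A list of class `eng_fixture_config`.
#' @export
study_fixture_config <- function(fs = 25000, epochs_per_class = 20,
                                 epoch_s = 3, gap_s = 0.5,
                                 target_snr_db = 5,
                                 informative_channels = c(1L, 5L, 9L),
                                 noise_channels = integer(),
                                 amp_drift = 0, rate_drift = 0,
                                 baseline_hz = 3, rate_scale = 1,
                                 seed = 1) {
  structure(list(fs = fs, epochs_per_class = epochs_per_class,
                 epoch_s = epoch_s, gap_s = gap_s,
                 target_snr_db = target_snr_db,
                 informative_channels = as.integer(informative_channels),
                 noise_channels = as.integer(noise_channels),
                 amp_drift = amp_drift, rate_drift = rate_drift,
                 baseline_hz = baseline_hz, rate_scale = rate_scale,
                 seed = as.integer(seed)),
            class = "eng_fixture_config")
}

#' Read a fixture configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [study_fixture_config()].
#'
#' @param path Path to a YAML file.
#' @return An `eng_fixture_config`.
#' @export
read_fixture_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_fixture_config, vals)
}

# the fixture's unit roster: seven units in three groups, each unit with a
# distinct waveform and its own pattern of class selectivity; palmar drives
# a double-peaked unit in the first group. Groups are laid out round-robin
# over the configured informative channels (3 + 2 + 2 with the default
# three channels).
fixture_units <- function(config) {
  shapes <- default_waveform_shapes(config$fs)
  ch <- config$informative_channels
  group <- c(1, 1, 1, 2, 2, 3, 3)
  chan <- ch[(group - 1) %% length(ch) + 1]
  b <- config$baseline_hz
  s <- config$rate_scale
  bump <- function(centers, sds, amps) {
    rate_profile(base_hz = b, centers_pct = centers, sds_pct = sds,
                 amps_hz = amps * s)
  }
  list(
    unit_spec("u1", chan[1], shapes$w1, b, list(
      little = bump(50, 15, 40))),
    unit_spec("u2", chan[2], shapes$w3, b, list(
      palmar = bump(c(25, 75), c(8, 8), c(30, 30)))),   # pre-shape + close
    unit_spec("u3", chan[3], shapes$w5, b, list(
      pinch = bump(50, 20, 35))),
    unit_spec("u4", chan[4], shapes$w2, b, list(
      palmar = bump(50, 18, 40))),
    unit_spec("u5", chan[5], shapes$w6, b, list(
      little = bump(30, 10, 25),
      pinch = bump(70, 10, 15))),
    unit_spec("u6", chan[6], shapes$w4, b, list(
      pinch = bump(40, 12, 40))),
    unit_spec("u7", chan[7], shapes$w7, b, list(
      little = bump(60, 15, 20),
      palmar = bump(50, 20, 10)))
  )
}

# scale a unit's waveform amplitude and bump rates for day-2 drift
drift_unit <- function(u, amp_factor, rate_factor) {
  u$shape$amplitude_uV <- u$shape$amplitude_uV * amp_factor
  u$class_rate_profiles <- lapply(u$class_rate_profiles, function(p) {
    p$amps_hz <- p$amps_hz * rate_factor
    p
  })
  u
}

#' Generate the two-day study fixture
#'
#' Renders one recording per day under [study_fixture_config()] conditions.
#' Day 2 applies the configured amplitude and rate drift to every unit and
#' uses its own derived seed (so zero drift gives statistically exchangeable,
#' not identical, days; pass `identical_days = TRUE` to reuse the day-1 seed
#' and obtain bit-identical days under zero drift).
#'
#' @param config An `eng_fixture_config`.
#' @param identical_days Reuse the day-1 seed for day 2.
#' @param days Which days to render (subset of `1:2`); single-day analyses
#'   can skip the cost of the other day.
#' @return List with elements `day1` and `day2` (`NULL` if not requested),
#'   each a `list(recording, truth)` as returned by [render_recording()],
#'   plus the `config`.
#' @export
make_study_fixture <- function(config = study_fixture_config(),
                               identical_days = FALSE, days = 1:2) {
  if (!inherits(config, "eng_fixture_config"))
    stop_invalid("config must come from study_fixture_config()")
  units1 <- fixture_units(config)
  units2 <- lapply(units1, drift_unit, amp_factor = 1 + config$amp_drift,
                   rate_factor = 1 + config$rate_drift)
  channels <- sort(unique(c(config$informative_channels,
                            config$noise_channels)))
  noise1 <- noise_spec(bandpass_hz = c(100, 10000),
                       target_snr_db = config$target_snr_db)
  local_seed(config$seed)
  day_seeds <- sample.int(.Machine$integer.max, 4)
  mk_day <- function(units, day_id, plan_seed, rec_seed, noise) {
    plan <- epoch_plan(epochs_per_class = config$epochs_per_class,
                       epoch_s = config$epoch_s, gap_s = config$gap_s,
                       seed = plan_seed)
    epochs <- build_epochs(plan)
    render_recording(units, epochs, noise, fs = config$fs, seed = rec_seed,
                     channels = channels, day_id = day_id)
  }
  day1 <- if (1 %in% days)
    mk_day(units1, "day1", day_seeds[1], day_seeds[2], noise1)
  day2 <- if (2 %in% days) {
    if (identical_days) {
      mk_day(units2, "day2", day_seeds[1], day_seeds[2], noise1)
    } else {
      # the noise level belongs to the electrode and amplifier, not to the
      # day: day 2 reuses day 1's realized per-channel noise sigmas, so
      # waveform drift changes the effective SNR instead of being absorbed
      # by a fresh calibration
      noise2 <- if (is.null(config$target_snr_db)) noise1
      else {
        d1 <- if (1 %in% days && !is.null(day1)) day1
        else mk_day(units1, "day1", day_seeds[1], day_seeds[2], noise1)
        noise_spec(sigma_uV = d1$recording$noise_sigma_uV,
                   bandpass_hz = c(100, 10000))
      }
      mk_day(units2, "day2", day_seeds[3], day_seeds[4], noise2)
    }
  }
  list(day1 = day1, day2 = day2, config = config)
}
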