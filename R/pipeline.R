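#' Run the full per-day decoding chain
#'
#' Convenience wrapper tying the stages together for one recording day:
#' per-channel noise estimation on the raw trace, translation-invariant
#' wavelet denoising, spike detection and template sorting on the denoised
#' channels, and epoch-wise relative spike-rate feature extraction. When a
#' template registry from a previous day is supplied, no new templates are
#' built and spikes are matched against it, which is what cross-day
#' evaluation without retraining requires.
#'
#' @param day `list(recording, truth)` from [render_recording()] or
#'   [make_study_fixture()] (the `truth` epochs supply the labels).
#' @param wavelet [wavelet_config()].
#' @param sorter [sorter_config()].
#' @param registry Optional day-1 template registry.
#' @param normalization Feature normalization, see [extract_features()].
#' @return List with `dataset` (`eng_dataset`), `sorting` (`eng_sorting`),
#'   `events` (flat table), `sigmas` (raw-trace noise levels), and the
#'   denoised `recording`.
#' @export
decode_day <- function(day, wavelet = wavelet_config(),
                       sorter = sorter_config(), registry = NULL,
                       normalization = "global") {
  rec <- day$recording
  sigmas <- vapply(seq_len(nrow(rec$data)), function(j)
    estimate_noise_sigma(rec$data[j, ], wavelet$family), numeric(1))
  names(sigmas) <- as.character(rec$channels)
  den <- denoise_recording(rec, wavelet)
  sorting <- sort_recording(den, sorter, sigmas = sigmas,
                            registry = registry)
  events <- sorted_events_table(sorting)
  reg <- if (is.null(registry)) sorting$registry else registry
  dataset <- extract_features(events, day$truth$epochs, reg,
                              normalization = normalization,
                              day_id = rec$day_id)
  list(dataset = dataset, sorting = sorting, events = events,
       sigmas = sigmas, recording = den)
}
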