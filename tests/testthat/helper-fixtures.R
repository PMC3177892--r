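# Shared fixture builders. Full-scale study fixtures are expensive to
# render, so they are memoised for the lifetime of the test session; every
# entry is keyed by its full configuration, never mutated by tests.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(config, days = 1:2, identical_days = FALSE) {
  key <- paste(c(unlist(config), days, identical_days), collapse = "|")
  if (!exists(key, .fixture_cache)) {
    assign(key, make_study_fixture(config, identical_days, days),
           .fixture_cache)
  }
  get(key, .fixture_cache)
}

# small single-channel recording: one unit per class-selective pattern,
# quick to render, used by denoise/sorter unit tests
small_channel_config <- function(seed, epochs_per_class = 2, epoch_s = 2,
                                 target_snr_db = 5) {
  study_fixture_config(epochs_per_class = epochs_per_class,
                       epoch_s = epoch_s, gap_s = 0.3,
                       informative_channels = 1L,
                       target_snr_db = target_snr_db, seed = seed)
}

# moderate 3-channel fixture used by decode/evaluate unit tests
small_study_config <- function(seed, ...) {
  study_fixture_config(epochs_per_class = 6, epoch_s = 2, gap_s = 0.3,
                       seed = seed, ...)
}

# events object constructed directly from snippet rows (bypasses detection)
synthetic_events <- function(snippets, fs = 25000, channel_id = 1L,
                             peak_index = NULL) {
  n <- nrow(snippets)
  if (is.null(peak_index)) peak_index <- seq_len(n) * 100L
  structure(list(
    table = data.frame(channel_id = rep(channel_id, n),
                       peak_index = peak_index,
                       peak_time_s = (peak_index - 1) / fs),
    snippets = snippets, fs = fs, snippet_ms = c(0.6, 1.0)),
    class = "eng_events")
}

# ground-truth spike table reshaped as a labeled event table
truth_as_events <- function(truth) {
  data.frame(channel_id = truth$spikes$channel_id,
             peak_time_s = truth$spikes$time_s,
             template_id = truth$spikes$unit_id,
             stringsAsFactors = FALSE)
}
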