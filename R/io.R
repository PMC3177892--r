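# On-disk layout for one recording day: a JSON header (sampling rate,
# channel ids, amplitude units, seed, day id), a raw IEEE-754 little-endian
# float64 matrix (channels x samples, channel-major), and CSV tables for
# the ground-truth spikes and the epoch log.

#' Write a recording (and optional ground truth) to disk
#'
#' @param x `list(recording, truth)` as returned by [render_recording()],
#'   or a bare `eng_recording`.
#' @param path Base path without extension; writes `<path>.json`,
#'   `<path>.f64`, and with ground truth `<path>_spikes.csv`,
#'   `<path>_epochs.csv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  rec <- if (inherits(x, "eng_recording")) x else x$recording
  truth <- if (inherits(x, "eng_recording")) NULL else x$truth
  header <- list(fs = rec$fs, channels = rec$channels, units = "uV",
                 day_id = rec$day_id, seed = rec$seed,
                 n_samples = ncol(rec$data),
                 byte_order = "little", dtype = "float64")
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".f64"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$data)), con, size = 8, endian = "little")
  if (!is.null(truth)) {
    write.csv(truth$spikes, paste0(path, "_spikes.csv"), row.names = FALSE)
    write.csv(truth$epochs, paste0(path, "_epochs.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Base path without extension.
#' @return List with `recording` (`eng_recording`) and, when the CSV tables
#'   exist, `truth` (spikes and epochs data.frames; the unit specs are not
#'   round-tripped).
#' @export
read_recording <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".f64"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = header$n_samples * length(header$channels),
                  size = 8, endian = "little")
  data <- matrix(vals, nrow = length(header$channels),
                 ncol = header$n_samples, byrow = TRUE)
  rownames(data) <- as.character(header$channels)
  rec <- structure(
    list(data = data, fs = header$fs,
         channels = as.integer(header$channels), day_id = header$day_id,
         units_uV = TRUE, seed = header$seed),
    class = "eng_recording")
  out <- list(recording = rec)
  spikes_path <- paste0(path, "_spikes.csv")
  if (file.exists(spikes_path)) {
    spikes <- read.csv(spikes_path, stringsAsFactors = FALSE)
    spikes$unit_id <- as.character(spikes$unit_id)
    epochs <- read.csv(paste0(path, "_epochs.csv"), stringsAsFactors = FALSE)
    out$truth <- structure(
      list(spikes = spikes, epochs = epochs, units = NULL,
           day_id = header$day_id),
      class = "eng_ground_truth")
  }
  out
}

#' Write templates to a JSON file
#'
#' @param registry Template registry from [sort_recording()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_templates <- function(registry, path) {
  out <- lapply(names(registry), function(ch) {
    lapply(registry[[ch]], function(tpl) {
      list(template_id = tpl$template_id, channel_id = tpl$channel_id,
           count = tpl$count, power = tpl$power,
           mean_waveform = tpl$mean_waveform)
    })
  })
  names(out) <- names(registry)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read templates written by [write_templates()]
#'
#' @param path JSON file.
#' @return Template registry (list of template lists keyed by channel id).
#' @export
read_templates <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(tpls) {
    lapply(tpls, function(tpl) {
      tpl$template_id <- as.integer(tpl$template_id)
      tpl$channel_id <- as.integer(tpl$channel_id)
      tpl$count <- as.integer(tpl$count)
      tpl$mean_waveform <- as.numeric(tpl$mean_waveform)
      tpl
    })
  })
}
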