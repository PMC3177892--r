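#' Spike detection and sorting configuration
#'
#' @param detect_threshold_multiplier Detection threshold as a multiple of
#'   the channel's robust noise level measured on the raw trace (default
#'   2 sigma). Detection runs on the denoised trace, where the residual
#'   noise floor is far below the raw sigma, so the multiplier sits between
#'   that floor and the smallest spike peaks (about 4-5 raw sigma at the
#'   SNR this pipeline targets).
#' @param dead_time_ms Minimum separation between detected events.
#' @param snippet_ms Length-2 vector `(pre, post)`: window cut around each
#'   aligned peak, in milliseconds.
#' @param min_correlation Minimum Pearson correlation between a snippet and
#'   a template mean for acceptance.
#' @param max_msd_over_power Maximum mean squared difference between snippet
#'   and template, normalized by the template's power (mean squared
#'   amplitude). Both similarity indexes must pass for an assignment; set
#'   this very large (or `min_correlation` to 0) to fall back on one index
#'   alone.
#' @param min_template_count Templates with fewer member spikes than this
#'   after the creation pass are discarded (their spikes end up unassigned
#'   in the matching step); prunes the tail of one-off clusters seeded by
#'   noise blips and overlap residues.
#' @return Object of class `eng_sorter_config`.
#' @export
sorter_config <- function(detect_threshold_multiplier = 2,
                          dead_time_ms = 1, snippet_ms = c(0.6, 1.0),
                          min_correlation = 0.8, max_msd_over_power = 2,
                          min_template_count = 5) {
  if (detect_threshold_multiplier <= 0 || dead_time_ms <= 0 ||
      any(snippet_ms <= 0) || max_msd_over_power <= 0)
    stop_invalid("sorter parameters must be positive")
  if (min_correlation >= 1)
    stop_invalid("min_correlation must be below 1")
  structure(list(detect_threshold_multiplier = detect_threshold_multiplier,
                 dead_time_ms = dead_time_ms, snippet_ms = snippet_ms,
                 min_correlation = min_correlation,
                 max_msd_over_power = max_msd_over_power,
                 min_template_count = min_template_count),
            class = "eng_sorter_config")
}

#' Threshold-crossing spike detection
#'
#' Events are local extrema of `|x|` exceeding `multiplier * sigma`,
#' separated by at least the dead time (larger peaks win within a dead-time
#' window, scanning in amplitude order). Snippets are cut peak-aligned;
#' events whose snippet window would leave the signal are dropped.
#'
#' @param x Denoised signal.
#' @param sigma Noise level of the channel (> 0), typically from
#'   [estimate_noise_sigma()] on the raw trace.
#' @param fs Sampling rate in Hz.
#' @param config [sorter_config()].
#' @param channel_id Channel identifier stored with the events.
#' @return Object of class `eng_events`: list with `table` (data.frame
#'   `channel_id`, `peak_index` 1-based, `peak_time_s`) and `snippets`
#'   (events x samples matrix), plus `fs` and `snippet_ms`.
#' @export
detect_spikes <- function(x, sigma, fs, config = sorter_config(),
                          channel_id = 1L) {
  if (sigma <= 0) stop_invalid("sigma must be positive")
  thr <- config$detect_threshold_multiplier * sigma
  a <- abs(x)
  n <- length(x)
  # local maxima of |x| above threshold
  cand <- which(a > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[a[cand] >= a[cand - 1] & a[cand] > a[cand + 1]]
  # enforce dead time, keeping the larger peak
  dead <- round(config$dead_time_ms / 1000 * fs)
  keep <- logical(length(cand))
  if (length(cand) > 0) {
    ord <- order(a[cand], decreasing = TRUE)
    taken <- rep(FALSE, n)
    for (i in ord) {
      p <- cand[i]
      lo <- max(1, p - dead); hi <- min(n, p + dead)
      if (!any(taken[lo:hi])) {
        keep[i] <- TRUE
        taken[p] <- TRUE
      }
    }
  }
  peaks <- sort(cand[keep])
  pre <- round(config$snippet_ms[1] / 1000 * fs)
  post <- round(config$snippet_ms[2] / 1000 * fs)
  inside <- peaks - pre >= 1 & peaks + post <= n
  peaks <- peaks[inside]
  snippets <- if (length(peaks) > 0) {
    t(vapply(peaks, function(p) x[(p - pre):(p + post)],
             numeric(pre + post + 1)))
  } else {
    matrix(numeric(), 0, pre + post + 1)
  }
  structure(list(
    table = data.frame(channel_id = rep(as.integer(channel_id),
                                        length(peaks)),
                       peak_index = peaks,
                       peak_time_s = (peaks - 1) / fs),
    snippets = snippets, fs = fs, snippet_ms = config$snippet_ms),
    class = "eng_events")
}

# similarity indexes between a snippet and a template mean waveform
snippet_correlation <- function(snippet, mean_waveform) {
  suppressWarnings(c0 <- stats::cor(snippet, mean_waveform))
  if (is.na(c0)) 0 else c0
}
snippet_msd <- function(snippet, mean_waveform) {
  mean((snippet - mean_waveform)^2)
}

# correlation and msd/power of one snippet against all templates in a
# w x K matrix (vectorized; called once per event in the sequential pass)
similarity_to_templates <- function(s, Tm, powers) {
  w <- length(s)
  sc <- s - mean(s)
  sn <- sqrt(sum(sc^2))
  Tc <- sweep(Tm, 2, colMeans(Tm))
  tn <- sqrt(colSums(Tc^2))
  cors <- as.numeric(crossprod(Tc, sc)) / (sn * tn)
  cors[!is.finite(cors)] <- 0
  msd <- (sum(s^2) + colSums(Tm^2) - 2 * as.numeric(crossprod(Tm, s))) / w
  list(cor = cors, msd_ratio = msd / powers)
}

#' Build spike templates by sequential assignment
#'
#' Single-pass online clustering: each event (in chronological order) is
#' compared with the running mean waveform of every existing template using
#' two similarity indexes, the Pearson correlation coefficient and the mean
#' squared difference normalized by the template's power. If the best
#' template (highest correlation) passes both acceptance thresholds the
#' event joins it and the running mean is updated; otherwise the event seeds
#' a new template. Templates are returned sorted by descending member count
#' and renumbered 1, 2, ...
#'
#' @param events `eng_events` from one channel, chronologically ordered.
#' @param config [sorter_config()].
#' @return List of templates, each with `template_id`, `channel_id`,
#'   `mean_waveform`, `power` (mean squared amplitude) and `count`.
#' @export
build_templates <- function(events, config = sorter_config()) {
  n <- nrow(events$table)
  if (n == 0) return(list())
  w <- ncol(events$snippets)
  Tm <- matrix(0, w, 0)      # template means, one column each
  counts <- integer(0)
  powers <- numeric(0)
  for (i in seq_len(n)) {
    s <- events$snippets[i, ]
    best <- NA_integer_
    if (ncol(Tm) > 0) {
      sim <- similarity_to_templates(s, Tm, powers)
      ord <- order(-sim$cor, sim$msd_ratio, seq_along(powers))
      cand <- ord[1]
      if (sim$cor[cand] >= config$min_correlation &&
          sim$msd_ratio[cand] <= config$max_msd_over_power)
        best <- cand
    }
    if (!is.na(best)) {
      Tm[, best] <- Tm[, best] + (s - Tm[, best]) / (counts[best] + 1)
      counts[best] <- counts[best] + 1L
      powers[best] <- mean(Tm[, best]^2)
    } else {
      Tm <- cbind(Tm, s)
      counts <- c(counts, 1L)
      powers <- c(powers, mean(s^2))
    }
  }
  keep <- which(counts >= config$min_template_count)
  keep <- keep[order(-counts[keep], keep)]
  channel_id <- if (n > 0) events$table$channel_id[1] else NA_integer_
  lapply(seq_along(keep), function(k) {
    j <- keep[k]
    list(template_id = k, channel_id = channel_id,
         mean_waveform = as.numeric(Tm[, j]), power = powers[j],
         count = counts[j])
  })
}

# index of the best acceptable template for a snippet, or NA
pick_template <- function(snippet, templates, config) {
  if (length(templates) == 0) return(NA_integer_)
  Tm <- vapply(templates, `[[`, numeric(length(snippet)), "mean_waveform")
  powers <- vapply(templates, `[[`, numeric(1), "power")
  ids <- vapply(templates, `[[`, integer(1), "template_id")
  sim <- similarity_to_templates(snippet, Tm, powers)
  # highest correlation; ties by lower msd/power, then lower template id
  ord <- order(-sim$cor, sim$msd_ratio, ids)
  best <- ord[1]
  if (sim$cor[best] >= config$min_correlation &&
      sim$msd_ratio[best] <= config$max_msd_over_power) best else NA_integer_
}

#' Assign detected spikes to templates
#'
#' Each event is labeled with the template maximizing the correlation
#' coefficient (ties broken by lower normalized mean squared difference,
#' then lower template id) provided both acceptance thresholds pass;
#' otherwise it is labeled `"unassigned"`.
#'
#' @param events `eng_events`.
#' @param templates Template list from [build_templates()] (non-empty).
#' @param config [sorter_config()].
#' @return The events object with a `template_id` column added to its table
#'   (integer as character, or `"unassigned"`).
#' @export
match_spikes <- function(events, templates, config = sorter_config()) {
  if (length(templates) == 0) stop_invalid("templates must be non-empty")
  width <- length(templates[[1]]$mean_waveform)
  if (ncol(events$snippets) != width && nrow(events$table) > 0)
    stop_invalid("snippet and template lengths differ")
  Tm <- vapply(templates, `[[`, numeric(width), "mean_waveform")
  Tm <- matrix(Tm, nrow = width)
  powers <- vapply(templates, `[[`, numeric(1), "power")
  ids <- vapply(templates, `[[`, integer(1), "template_id")
  labels <- character(nrow(events$table))
  for (i in seq_len(nrow(events$table))) {
    sim <- similarity_to_templates(events$snippets[i, ], Tm, powers)
    ord <- order(-sim$cor, sim$msd_ratio, ids)
    best <- ord[1]
    labels[i] <- if (sim$cor[best] >= config$min_correlation &&
                     sim$msd_ratio[best] <= config$max_msd_over_power)
      as.character(ids[best]) else "unassigned"
  }
  events$table$template_id <- labels
  events
}

#' Detect, template and label the spikes of every channel
#'
#' Runs the full per-channel sorting chain on a (denoised) recording:
#' noise-level estimation, threshold detection, sequential template
#' creation, and template matching. Templates are kept per channel; no
#' cross-channel sharing, since each intrafascicular site sees different
#' fibers.
#'
#' @param recording Denoised `eng_recording`.
#' @param config [sorter_config()].
#' @param sigmas Optional named numeric vector of per-channel noise levels
#'   (names = channel ids), e.g. estimated from the raw recording;
#'   estimated from the given data when `NULL`.
#' @param registry Optional template registry from a previous run (e.g. day
#'   1); when supplied, no new templates are built and spikes are matched
#'   against it.
#' @return Object of class `eng_sorting`: list with `events` (one
#'   `eng_events` per channel, labeled), `registry` (list of template lists
#'   keyed by channel id), `config`.
#' @export
sort_recording <- function(recording, config = sorter_config(),
                           sigmas = NULL, registry = NULL) {
  events <- list()
  new_registry <- list()
  for (j in seq_along(recording$channels)) {
    ch <- recording$channels[j]
    key <- as.character(ch)
    x <- recording$data[j, ]
    sigma <- if (!is.null(sigmas) && key %in% names(sigmas)) sigmas[[key]]
    else estimate_noise_sigma(x)
    if (sigma <= 0) sigma <- .Machine$double.eps
    ev <- detect_spikes(x, sigma, recording$fs, config, channel_id = ch)
    tpls <- if (is.null(registry)) build_templates(ev, config)
    else if (key %in% names(registry)) registry[[key]] else list()
    if (length(tpls) > 0) {
      ev <- match_spikes(ev, tpls, config)
    } else {
      ev$table$template_id <- rep("unassigned", nrow(ev$table))
    }
    events[[key]] <- ev
    new_registry[[key]] <- tpls
  }
  structure(list(events = events, registry = new_registry, config = config),
            class = "eng_sorting")
}

#' Flatten a sorting result into one event table
#'
#' @param sorting `eng_sorting` from [sort_recording()].
#' @return data.frame with `channel_id`, `peak_time_s`, `template_id`,
#'   sorted by time.
#' @export
sorted_events_table <- function(sorting) {
  tab <- do.call(rbind, lapply(sorting$events, `[[`, "table"))
  if (is.null(tab))
    return(data.frame(channel_id = integer(), peak_time_s = numeric(),
                      template_id = character()))
  tab <- tab[order(tab$peak_time_s), c("channel_id", "peak_time_s",
                                       "template_id")]
  rownames(tab) <- NULL
  tab
}
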