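#' Match detected events against ground-truth spikes
#'
#' Greedy one-to-one matching in time: each ground-truth spike on a channel
#' is paired with the closest unmatched detection within the tolerance.
#' Used to score the sorter against the simulator's known spike trains.
#'
#' @param events Event table with `channel_id`, `peak_time_s` (and
#'   optionally `template_id`).
#' @param truth `eng_ground_truth` or its `spikes` data.frame.
#' @param tol_s Matching tolerance in seconds, default 0.5 ms.
#' @return List with `sensitivity` (matched truth spikes / truth spikes),
#'   `false_positive_rate` (unmatched detections / detections), `pairs`
#'   (data.frame `unit_id`, `channel_id`, `truth_time_s`, `event_row`,
#'   `peak_time_s`, and `template_id` when present), `n_truth`, `n_events`.
#' @export
score_detection <- function(events, truth, tol_s = 5e-4) {
  spikes <- if (inherits(truth, "eng_ground_truth")) truth$spikes else truth
  n_truth <- nrow(spikes)
  n_events <- nrow(events)
  pairs <- list()
  matched_event <- rep(FALSE, n_events)
  for (ch in unique(spikes$channel_id)) {
    tr <- spikes[spikes$channel_id == ch, , drop = FALSE]
    ev_rows <- which(events$channel_id == ch)
    if (length(ev_rows) == 0) next
    ev_times <- events$peak_time_s[ev_rows]
    taken <- rep(FALSE, length(ev_rows))
    for (i in seq_len(nrow(tr))) {
      d <- abs(ev_times - tr$time_s[i])
      d[taken] <- Inf
      j <- which.min(d)
      if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol_s) {
        taken[j] <- TRUE
        matched_event[ev_rows[j]] <- TRUE
        pairs[[length(pairs) + 1]] <- data.frame(
          unit_id = tr$unit_id[i], channel_id = ch,
          truth_time_s = tr$time_s[i], event_row = ev_rows[j],
          peak_time_s = ev_times[j],
          template_id = if ("template_id" %in% names(events))
            events$template_id[ev_rows[j]] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs)
  else data.frame(unit_id = character(), channel_id = integer(),
                  truth_time_s = numeric(), event_row = integer(),
                  peak_time_s = numeric(), template_id = character(),
                  stringsAsFactors = FALSE)
  list(sensitivity = if (n_truth > 0) nrow(pairs) / n_truth else NA_real_,
       false_positive_rate = if (n_events > 0)
         sum(!matched_event) / n_events else NA_real_,
       pairs = pairs, n_truth = n_truth, n_events = n_events)
}

#' Template-assignment accuracy against ground truth
#'
#' Maps each (channel, template) to its majority ground-truth unit among the
#' matched, assigned events and reports the fraction of those events whose
#' unit agrees with their template's majority unit (cluster purity over all
#' assigned matched spikes). Matched events labeled `"unassigned"` count as
#' errors when `count_unassigned = TRUE` (the default), since a missed
#' assignment loses the spike for decoding.
#'
#' @param score Result of [score_detection()] on labeled events.
#' @param count_unassigned Whether unassigned matched spikes count against
#'   the accuracy.
#' @return List with `accuracy`, `purity_per_template` (data.frame
#'   `channel_id`, `template_id`, `unit_id`, `n`, `purity`), and
#'   `unassigned_fraction`.
#' @export
assignment_accuracy <- function(score, count_unassigned = TRUE) {
  p <- score$pairs
  if (nrow(p) == 0)
    return(list(accuracy = NA_real_, purity_per_template = NULL,
                unassigned_fraction = NA_real_))
  unassigned <- p$template_id == "unassigned" | is.na(p$template_id)
  q <- p[!unassigned, , drop = FALSE]
  if (nrow(q) == 0)
    return(list(accuracy = 0, purity_per_template = NULL,
                unassigned_fraction = 1))
  key <- interaction(q$channel_id, q$template_id, drop = TRUE)
  per <- lapply(split(q, key), function(g) {
    tab <- sort(table(g$unit_id), decreasing = TRUE)
    data.frame(channel_id = g$channel_id[1], template_id = g$template_id[1],
               unit_id = names(tab)[1], n = nrow(g),
               purity = as.numeric(tab[1]) / nrow(g),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  correct <- sum(per$n * per$purity)
  denom <- if (count_unassigned) nrow(p) else nrow(q)
  list(accuracy = correct / denom, purity_per_template = per,
       unassigned_fraction = sum(unassigned) / nrow(p))
}
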