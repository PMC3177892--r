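#' Define a task set
#'
#' A task set is the subset of movement classes a classifier has to
#' separate, e.g. "rest vs little vs pinch vs palmar" or the binary "rest vs
#' activity" task in which the three movements are merged into a single
#' activity class.
#'
#' @param classes Classes included (>= 2), or exactly
#'   `c("rest", "activity")` for the merged binary task.
#' @param name Optional display name; defaults to the classes joined by
#'   " vs ".
#' @return Object of class `eng_task_set`.
#' @export
task_set <- function(classes, name = NULL) {
  merged <- identical(sort(classes), sort(c("rest", "activity")))
  if (!merged && !all(classes %in% grip_classes()))
    stop_invalid("unknown class in task set")
  if (length(classes) < 2) stop_invalid("a task set needs >= 2 classes")
  if (is.null(name)) name <- paste(classes, collapse = " vs ")
  structure(list(classes = classes, name = name, merged = merged),
            class = "eng_task_set")
}

#' The task sets of the study design
#'
#' Rest paired with each single movement, each movement pair, all three
#' movements, and the binary rest-vs-activity task.
#'
#' @return Named list of [task_set()] objects.
#' @export
standard_task_sets <- function() {
  sets <- list(
    task_set(c("rest", "little")),
    task_set(c("rest", "palmar")),
    task_set(c("rest", "pinch")),
    task_set(c("rest", "little", "palmar")),
    task_set(c("rest", "little", "pinch")),
    task_set(c("rest", "pinch", "palmar")),
    task_set(c("rest", "little", "pinch", "palmar")),
    task_set(c("rest", "activity"))
  )
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

# restrict a dataset to a task set's epochs (and merge labels if needed);
# returns NULL if a requested class is absent
restrict_task <- function(dataset, ts) {
  y <- as.character(dataset$y)
  if (ts$merged) {
    y[y %in% c("little", "palmar", "pinch")] <- "activity"
    keep <- y %in% c("rest", "activity")
    lev <- c("rest", "activity")
  } else {
    keep <- y %in% ts$classes
    lev <- intersect(grip_classes(), ts$classes)
  }
  if (!all(lev %in% y[keep])) return(NULL)
  out <- dataset
  out$X <- dataset$X[keep, , drop = FALSE]
  out$y <- factor(y[keep], levels = lev)
  out$epoch_id <- dataset$epoch_id[keep]
  out$zero_epochs <- dataset$zero_epochs[keep]
  out
}

#' Leave-one-out recognition ratio per task set
#'
#' @param dataset `eng_dataset`.
#' @param task_sets List of [task_set()] objects.
#' @param config [svm_config()].
#' @return data.frame with `task`, `n_epochs`, `rr` (`NA` when a requested
#'   class is absent from the data, marking the cell not evaluable).
#' @export
evaluate_task_sets <- function(dataset, task_sets = standard_task_sets(),
                               config = svm_config()) {
  rows <- lapply(task_sets, function(ts) {
    sub <- restrict_task(dataset, ts)
    if (is.null(sub))
      return(data.frame(task = ts$name, n_epochs = 0L, rr = NA_real_))
    res <- loo_validate(sub, config = config)
    data.frame(task = ts$name, n_epochs = length(sub$y), rr = res$rr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exhaustive channel-subset search
#'
#' Enumerates every non-empty subset of the dataset's channels up to
#' `max_subset_size`, restricts and re-normalizes the features to each
#' subset, and computes the leave-one-out recognition ratio on the given
#' task. Returns the best subset (ties broken by smaller size, then
#' lexicographic channel order), the full table, and the best-rr-per-size
#' curve. More channels add information up to a point, after which the
#' growing feature dimension relative to the fixed number of epochs lets
#' overfitting erode the ratio.
#'
#' @param dataset `eng_dataset` with features from all candidate channels.
#' @param ts [task_set()] to evaluate.
#' @param max_subset_size Largest subset size to enumerate (>= 1).
#' @param config [svm_config()].
#' @return List with `best_channels`, `best_rr`, `table` (data.frame
#'   `subset`, `size`, `rr`), `curve` (data.frame `size`, `max_rr`).
#' @export
channel_subset_search <- function(dataset, ts, max_subset_size = NULL,
                                  config = svm_config()) {
  channels <- sort(unique(dataset$feature_info$channel_id))
  if (is.null(max_subset_size)) max_subset_size <- length(channels)
  if (max_subset_size < 1) stop_invalid("max_subset_size must be >= 1")
  max_subset_size <- min(max_subset_size, length(channels))
  subsets <- unlist(lapply(seq_len(max_subset_size), function(k)
    combn(channels, k, simplify = FALSE)), recursive = FALSE)
  rr <- vapply(subsets, function(subset) {
    sub <- restrict_task(restrict_channels(dataset, subset), ts)
    if (is.null(sub)) return(NA_real_)
    loo_validate(sub, config = config)$rr
  }, numeric(1))
  sizes <- lengths(subsets)
  tab <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = sizes, rr = rr)
  # argmax with deterministic tie-breaks: higher rr, smaller subset,
  # lexicographic channel order (enumeration order is lexicographic per size)
  ord <- order(-rr, sizes, seq_along(subsets))
  best <- ord[1]
  curve <- do.call(rbind, lapply(sort(unique(sizes)), function(k)
    data.frame(size = k, max_rr = max(rr[sizes == k], na.rm = TRUE))))
  list(best_channels = subsets[[best]], best_rr = rr[best], table = tab,
       curve = curve)
}

#' Cross-day evaluation with and without retraining
#'
#' Day-to-day robustness of the decoder: the "no retraining" scheme fits the
#' classifier on all day-1 epochs and tests it on all day-2 epochs, while
#' the "retraining" scheme is leave-one-out within day 2. Both days must
#' share the template registry (templates built on day 1, day-2 spikes
#' matched against them), otherwise the feature spaces are incomparable.
#'
#' @param ds1,ds2 `eng_dataset` objects for day 1 and day 2 with identical
#'   feature spaces.
#' @param task_sets List of [task_set()] objects.
#' @param config [svm_config()].
#' @return data.frame with `task`, `rr_no_retraining`, `rr_retraining`.
#' @export
cross_day_evaluate <- function(ds1, ds2, task_sets = standard_task_sets(),
                               config = svm_config()) {
  if (length(ds2$y) == 0) stop_invalid("day-2 dataset is empty")
  if (!identical(ds1$feature_info$name, ds2$feature_info$name))
    stop_invalid("day-1 and day-2 feature registries differ")
  rows <- lapply(task_sets, function(ts) {
    s1 <- restrict_task(ds1, ts)
    s2 <- restrict_task(ds2, ts)
    if (is.null(s1) || is.null(s2))
      return(data.frame(task = ts$name, rr_no_retraining = NA_real_,
                        rr_retraining = NA_real_))
    m <- train_classifier(s1, config = config)
    pred <- predict_classes(m, s2$X)
    rr_fixed <- mean(as.character(pred) == as.character(s2$y))
    rr_retrain <- loo_validate(s2, config = config)$rr
    data.frame(task = ts$name, rr_no_retraining = rr_fixed,
               rr_retraining = rr_retrain)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalized firing-rate profiles per class and template
#'
#' Maps each epoch's spike times to normalized epoch time (0-100%), bins
#' them, and reports the mean and standard deviation across the epochs of
#' each class, in spikes/s. This is the rate-profile view in which
#' class-specific modulation (e.g. the double-peaked palmar profile) becomes
#' visible.
#'
#' @param events Event table with `channel_id`, `peak_time_s`,
#'   `template_id` (unassigned spikes are ignored), or any spike table with
#'   those columns (e.g. ground truth with `unit_id` renamed).
#' @param epochs Fixed-width epoch table.
#' @param n_bins Number of bins over 0-100% (>= 2), default 50.
#' @param classes Classes to profile; defaults to those present in the
#'   epoch table. A requested class without epochs is omitted with a
#'   warning.
#' @return data.frame with `class`, `channel_id`, `template_id`,
#'   `bin_center_pct`, `mean_hz`, `sd_hz`.
#' @export
rate_profiles <- function(events, epochs, n_bins = 50,
                          classes = unique(epochs$class)) {
  if (n_bins < 2) stop_invalid("n_bins must be >= 2")
  empty <- data.frame(class = character(), channel_id = integer(),
                      template_id = character(), bin_center_pct = numeric(),
                      mean_hz = numeric(), sd_hz = numeric())
  if (nrow(epochs) == 0) return(empty)
  widths <- epochs$end_s - epochs$start_s
  if (diff(range(widths)) > 1e-9)
    stop_invalid("epochs must have a fixed width")
  epoch_s <- widths[1]
  bin_w_s <- epoch_s / n_bins
  ev <- events[events$template_id != "unassigned", , drop = FALSE]
  keys <- unique(ev[, c("channel_id", "template_id")])
  keys <- keys[order(keys$channel_id, keys$template_id), , drop = FALSE]
  out <- list()
  for (cls in classes) {
    ep <- epochs[epochs$class == cls, , drop = FALSE]
    if (nrow(ep) == 0) {
      warning("no epochs for class ", cls)
      next
    }
    for (r in seq_len(nrow(keys))) {
      sel <- ev$channel_id == keys$channel_id[r] &
        ev$template_id == keys$template_id[r]
      times <- ev$peak_time_s[sel]
      counts <- matrix(0, nrow(ep), n_bins)
      for (i in seq_len(nrow(ep))) {
        inside <- times >= ep$start_s[i] & times < ep$end_s[i]
        if (!any(inside)) next
        pct <- (times[inside] - ep$start_s[i]) / epoch_s
        b <- pmin(floor(pct * n_bins) + 1, n_bins)
        counts[i, ] <- tabulate(b, n_bins)
      }
      rates <- counts / bin_w_s
      out[[length(out) + 1]] <- data.frame(
        class = cls, channel_id = keys$channel_id[r],
        template_id = keys$template_id[r],
        bin_center_pct = (seq_len(n_bins) - 0.5) / n_bins * 100,
        mean_hz = colMeans(rates),
        sd_hz = apply(rates, 2, sd))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Count peaks in a mean rate profile
#'
#' Simple local-maximum scan: the profile is smoothed with a short running
#' mean, local maxima are found, maxima below `min_height_frac` of the
#' profile maximum are discarded, and maxima closer than `min_separation`
#' bins keep only the larger one.
#'
#' @param mean_hz Mean rate profile over bins.
#' @param smooth_bins Width of the running-mean smoother (odd), default 5.
#' @param min_height_frac Minimum peak height as a fraction of the profile
#'   maximum, default 0.5.
#' @param min_separation Minimum distance between peaks in bins.
#' @return Integer number of peaks.
#' @export
count_profile_peaks <- function(mean_hz, smooth_bins = 5,
                                min_height_frac = 0.5, min_separation = 5) {
  n <- length(mean_hz)
  if (n < 3 || max(mean_hz) == 0) return(0L)
  half <- smooth_bins %/% 2
  s <- vapply(seq_len(n), function(i)
    mean(mean_hz[max(1, i - half):min(n, i + half)]), numeric(1))
  is_peak <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] &
                 s[2:(n - 1)] >= s[3:n], FALSE)
  peaks <- which(is_peak & s >= min_height_frac * max(s))
  if (length(peaks) < 2) return(length(peaks))
  kept <- peaks[1]
  for (p in peaks[-1]) {
    if (p - kept[length(kept)] >= min_separation) kept <- c(kept, p)
    else if (s[p] > s[kept[length(kept)]]) kept[length(kept)] <- p
  }
  length(kept)
}
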