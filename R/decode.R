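#' Epoch-wise relative spike-rate features
#'
#' For every labeled epoch, the feature vector F holds, per (channel,
#' template) pair of the active channel set, the number of spikes assigned
#' to that template within the epoch divided by the total number of
#' assigned spikes in the epoch across the active channels. Absolute rates
#' are deliberately discarded: classification should rely on which
#' waveforms fire relative to each other ("quality" of activity), not on
#' how much overall activity there is. Unassigned spikes match no template
#' waveform and are excluded from numerator and denominator alike. Epochs
#' without any assigned spike get the all-zero vector and are flagged.
#'
#' @param events Event table ([sorted_events_table()]) with `channel_id`,
#'   `peak_time_s`, `template_id`.
#' @param epochs Epoch table (`epoch_id`, `start_s`, `end_s`, `class`).
#' @param registry Template registry (list keyed by channel id) declaring
#'   the feature space; every (channel, template) pair becomes one feature.
#' @param channel_set Channels to use; defaults to all registry channels.
#' @param normalization `"global"` (denominator = all assigned spikes on
#'   the active channels, the default) or `"per_channel"` (each channel's
#'   features sum to 1 separately).
#' @param day_id Recording-day identifier stored with the dataset.
#' @return Object of class `eng_dataset`: list with `X` (epochs x features
#'   matrix), `y` (factor with the fixed class order), `epoch_id`, `day_id`,
#'   `zero_epochs` (logical flag), `feature_info` (data.frame `channel_id`,
#'   `template_id`, `name`), `channel_set`, `normalization`.
#' @export
extract_features <- function(events, epochs, registry, channel_set = NULL,
                             normalization = c("global", "per_channel"),
                             day_id = "day1") {
  normalization <- match.arg(normalization)
  reg_channels <- as.integer(names(registry))
  if (is.null(channel_set)) channel_set <- reg_channels
  channel_set <- sort(as.integer(channel_set))
  feature_info <- do.call(rbind, lapply(channel_set, function(ch) {
    tpls <- registry[[as.character(ch)]]
    if (is.null(tpls) || length(tpls) == 0) return(NULL)
    data.frame(channel_id = ch,
               template_id = vapply(tpls, `[[`, integer(1), "template_id"))
  }))
  if (is.null(feature_info) || nrow(feature_info) == 0)
    stop_invalid("registry has no templates on the requested channels")
  feature_info$name <- sprintf("ch%d_t%d", feature_info$channel_id,
                               feature_info$template_id)

  ev <- events[events$template_id != "unassigned" &
                 events$channel_id %in% channel_set, , drop = FALSE]
  if (nrow(ev) > 0) {
    key <- sprintf("ch%s_t%s", ev$channel_id, ev$template_id)
    if (!all(key %in% feature_info$name))
      stop_invalid("event labeled with a template absent from the registry")
  }
  n_ep <- nrow(epochs)
  X <- matrix(0, n_ep, nrow(feature_info),
              dimnames = list(NULL, feature_info$name))
  for (i in seq_len(n_ep)) {
    inside <- ev$peak_time_s >= epochs$start_s[i] &
      ev$peak_time_s < epochs$end_s[i]
    if (!any(inside)) next
    counts <- table(factor(sprintf("ch%s_t%s", ev$channel_id[inside],
                                   ev$template_id[inside]),
                           levels = feature_info$name))
    X[i, ] <- as.numeric(counts)
  }
  X <- normalize_features(X, feature_info, normalization)
  zero <- rowSums(X) == 0
  y <- factor(epochs$class,
              levels = intersect(c(grip_classes(), "activity"),
                                 unique(epochs$class)))
  structure(list(X = X, y = y, epoch_id = epochs$epoch_id, day_id = day_id,
                 zero_epochs = zero, feature_info = feature_info,
                 channel_set = channel_set, normalization = normalization),
            class = "eng_dataset")
}

# turn raw counts into relative rates under the chosen normalization
normalize_features <- function(X, feature_info, normalization) {
  if (normalization == "global") {
    tot <- rowSums(X)
    sel <- tot > 0
    X[sel, ] <- X[sel, , drop = FALSE] / tot[sel]
  } else {
    for (ch in unique(feature_info$channel_id)) {
      cols <- which(feature_info$channel_id == ch)
      tot <- rowSums(X[, cols, drop = FALSE])
      sel <- tot > 0
      X[sel, cols] <- X[sel, cols, drop = FALSE] / tot[sel]
    }
  }
  X
}

#' Restrict a dataset to a channel subset
#'
#' Drops the features of the other channels and re-normalizes each epoch's
#' remaining counts so the relative-rate definition is preserved within the
#' subset. Epochs left without assigned spikes become all-zero.
#'
#' @param dataset `eng_dataset` with global normalization.
#' @param channels Channels to keep.
#' @return A new `eng_dataset`.
#' @export
restrict_channels <- function(dataset, channels) {
  keep <- dataset$feature_info$channel_id %in% channels
  if (!any(keep)) stop_invalid("no features on the requested channels")
  X <- dataset$X[, keep, drop = FALSE]
  info <- dataset$feature_info[keep, , drop = FALSE]
  X <- normalize_features(X, info, dataset$normalization)
  out <- dataset
  out$X <- X
  out$feature_info <- info
  out$channel_set <- intersect(dataset$channel_set, channels)
  out$zero_epochs <- rowSums(X) == 0
  out
}

#' SVM classifier configuration
#'
#' One-against-one multiclass support vector machine. By default an RBF
#' kernel with fixed hyperparameters is used so that every fit is
#' deterministic and cheap; setting `tune = TRUE` enables an inner
#' cross-validated grid search on the training fold only.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param cost Regularization parameter C (> 0).
#' @param gamma RBF kernel width; `NULL` uses the variance-scaled default
#'   `1 / (n_features * var(X))`, which keeps the kernel informative for
#'   simplex-normalized features whose entries live well inside \[0, 1\].
#' @param tune Run an inner `tune_folds`-fold grid search over
#'   `cost_grid` x `gamma_grid` on each training set.
#' @param cost_grid,gamma_grid Hyperparameter grids for tuning.
#' @param tune_folds Folds of the inner search.
#' @return Object of class `eng_svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), cost = 10, gamma = NULL,
                       tune = FALSE, cost_grid = c(0.1, 1, 10, 100),
                       gamma_grid = c(0.01, 0.1, 1), tune_folds = 5) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop_invalid("cost must be positive")
  if (!is.null(gamma) && gamma <= 0) stop_invalid("gamma must be positive")
  structure(list(kernel = kernel, cost = cost, gamma = gamma, tune = tune,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 tune_folds = tune_folds),
            class = "eng_svm_config")
}

#' Train a one-against-one SVM ensemble
#'
#' Fits one binary SVM (LIBSVM via e1071) per unordered class pair;
#' prediction is by majority vote with ties broken by the fixed class order
#' (rest < little < palmar < pinch). With two classes the ensemble is
#' exactly the single binary classifier.
#'
#' @param X Feature matrix (epochs x features) or an `eng_dataset`.
#' @param y Class factor (ignored when `X` is a dataset).
#' @param config [svm_config()].
#' @return Object of class `eng_ovo_svm`.
#' @export
train_classifier <- function(X, y = NULL, config = svm_config()) {
  if (inherits(X, "eng_dataset")) {
    y <- X$y
    X <- X$X
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop_invalid("at least 2 classes are required")
  if (nrow(X) != length(y)) stop_invalid("X and y sizes differ")
  if (config$tune) {
    config <- tune_svm_config(X, y, config)
  }
  gamma <- if (is.null(config$gamma)) default_gamma(X) else config$gamma
  classes <- levels(y)
  pairs <- combn(classes, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    e1071::svm(x = X[sel, , drop = FALSE],
               y = factor(y[sel], levels = pr),
               kernel = if (config$kernel == "rbf") "radial" else "linear",
               cost = config$cost, gamma = gamma, scale = FALSE)
  })
  structure(list(fits = fits, pairs = pairs, classes = classes,
                 n_features = ncol(X), config = config),
            class = "eng_ovo_svm")
}

# variance-scaled kernel width (the "scale" convention)
default_gamma <- function(X) {
  v <- var(as.numeric(X))
  if (!is.finite(v) || v <= 0) return(1 / ncol(X))
  1 / (ncol(X) * v)
}

# inner cross-validated grid search; evaluated with the ovo ensemble itself
tune_svm_config <- function(X, y, config) {
  folds <- make_folds(length(y), config$tune_folds, y)
  best <- NULL
  best_acc <- -Inf
  for (g in config$gamma_grid) {
    for (cst in config$cost_grid) {
      cand <- config
      cand$tune <- FALSE
      cand$cost <- cst
      cand$gamma <- g
      correct <- 0
      for (f in unique(folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) next
        m <- train_classifier(X[tr, , drop = FALSE], y[tr], cand)
        correct <- correct +
          sum(predict_classes(m, X[!tr, , drop = FALSE]) == y[!tr])
      }
      if (correct / length(y) > best_acc) {
        best_acc <- correct / length(y)
        best <- cand
      }
    }
  }
  best
}

# deterministic stratified fold assignment (no RNG: epochs are already in
# randomized cue order)
make_folds <- function(n, k, y) {
  folds <- integer(n)
  for (cls in levels(y)) {
    idx <- which(y == cls)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Predict classes with a one-against-one ensemble
#'
#' @param model `eng_ovo_svm` from [train_classifier()].
#' @param X Feature matrix with the training feature dimension.
#' @return Factor of predicted labels (training class levels).
#' @export
predict_classes <- function(model, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0)
    return(factor(character(), levels = model$classes))
  if (ncol(X) != model$n_features)
    stop_invalid("feature dimension differs from training")
  votes <- matrix(0L, nrow(X), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (i in seq_along(model$fits)) {
    pred <- as.character(predict(model$fits[[i]], X))
    for (cls in model$pairs[[i]])
      votes[, cls] <- votes[, cls] + (pred == cls)
  }
  # majority vote; ties go to the earliest class in the fixed order
  idx <- apply(votes, 1, which.max)
  factor(model$classes[idx], levels = model$classes)
}

#' Leave-one-out validation
#'
#' For each epoch, the classifier is trained on the remaining epochs and
#' predicts the held-out one. The recognition ratio is the fraction of
#' epochs whose class is correctly identified; the confusion matrix has
#' true classes as rows.
#'
#' @param X Feature matrix or `eng_dataset`.
#' @param y Class factor (ignored for a dataset).
#' @param config [svm_config()].
#' @return List with `rr`, `confusion`, `predicted`, `truth`.
#' @export
loo_validate <- function(X, y = NULL, config = svm_config()) {
  if (inherits(X, "eng_dataset")) {
    y <- X$y
    X <- X$X
  }
  y <- droplevels(as.factor(y))
  n <- length(y)
  if (n < nlevels(y) + 1)
    stop_invalid("need at least one more epoch than classes")
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    tr_y <- y[-i]
    if (length(unique(tr_y)) < 2) next
    m <- train_classifier(X[-i, , drop = FALSE], droplevels(tr_y), config)
    p <- as.character(predict_classes(m, X[i, , drop = FALSE]))
    pred[i] <- p
  }
  rr <- mean(pred == y, na.rm = FALSE)
  confusion <- table(truth = y, predicted = pred)
  list(rr = rr, confusion = confusion, predicted = pred, truth = y)
}
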