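# hand-built registry with one or more templates per channel
toy_registry <- function(spec) {
  # spec: named list channel -> number of templates
  out <- lapply(names(spec), function(ch) {
    lapply(seq_len(spec[[ch]]), function(k)
      list(template_id = k, channel_id = as.integer(ch),
           mean_waveform = rep(0, 10), power = 1, count = 10L))
  })
  names(out) <- names(spec)
  out
}

toy_epochs <- function(classes, epoch_s = 1) {
  n <- length(classes)
  data.frame(epoch_id = seq_len(n), start_s = (seq_len(n) - 1) * epoch_s,
             end_s = seq_len(n) * epoch_s, class = classes,
             stringsAsFactors = FALSE)
}

toy_events <- function(epoch_idx, channel, template, epoch_s = 1) {
  n <- length(epoch_idx)
  data.frame(channel_id = rep(channel, n),
             peak_time_s = (epoch_idx - 1) * epoch_s +
               seq(0.05, 0.95, length.out = n),
             template_id = as.character(template),
             stringsAsFactors = FALSE)
}

test_that("relative spike-rate features are count ratios", {
  reg <- toy_registry(list(`1` = 3))
  ep <- toy_epochs("palmar")
  ev <- toy_events(rep(1, 5), 1L, c(1, 1, 1, 2, 3))
  ds <- extract_features(ev, ep, reg)
  expect_equal(as.numeric(ds$X), c(0.6, 0.2, 0.2))
  # duplicating every spike leaves the ratios unchanged
  ev2 <- rbind(ev, ev)
  ds2 <- extract_features(ev2, ep, reg)
  expect_equal(ds2$X, ds$X)
  # single template: F = 1
  reg1 <- toy_registry(list(`1` = 1))
  ds3 <- extract_features(toy_events(rep(1, 4), 1L, rep(1, 4)), ep, reg1)
  expect_equal(as.numeric(ds3$X), 1)
})

test_that("unassigned spikes and zero-spike epochs are handled", {
  reg <- toy_registry(list(`1` = 2))
  ep <- toy_epochs(c("rest", "pinch"))
  ev <- toy_events(rep(1, 4), 1L, c(1, 1, 2, "unassigned"))
  ds <- extract_features(ev, ep, reg)
  # unassigned excluded from numerator and denominator
  expect_equal(as.numeric(ds$X[1, ]), c(2 / 3, 1 / 3))
  # epoch 2 has no spikes: all-zero and flagged
  expect_equal(as.numeric(ds$X[2, ]), c(0, 0))
  expect_identical(ds$zero_epochs, c(FALSE, TRUE))
  # template missing from the registry is an error
  bad <- toy_events(rep(1, 2), 1L, c(1, 9))
  expect_error(extract_features(bad, ep, reg), "registry")
})

test_that("feature normalization options sum correctly", {
  reg <- toy_registry(list(`1` = 2, `2` = 1))
  ep <- toy_epochs(c("rest", "little", "palmar", "pinch"))
  set.seed(21)
  ev <- do.call(rbind, lapply(1:4, function(i)
    rbind(toy_events(rep(i, 3), 1L, sample(1:2, 3, TRUE)),
          toy_events(rep(i, 2), 2L, c(1, 1)))))
  g <- extract_features(ev, ep, reg, normalization = "global")
  expect_true(all(abs(rowSums(g$X) - 1) < 1e-12))
  p <- extract_features(ev, ep, reg, normalization = "per_channel")
  expect_true(all(abs(rowSums(p$X[, 1:2]) - 1) < 1e-12))
  expect_true(all(abs(p$X[, 3] - 1) < 1e-12))
})

test_that("channel restriction re-normalizes the remaining features", {
  reg <- toy_registry(list(`1` = 2, `2` = 2))
  ep <- toy_epochs("little")
  ev <- rbind(toy_events(rep(1, 3), 1L, c(1, 1, 2)),
              toy_events(rep(1, 1), 2L, 1))
  ds <- extract_features(ev, ep, reg)
  expect_equal(as.numeric(ds$X), c(0.5, 0.25, 0.25, 0))
  r <- restrict_channels(ds, 1L)
  expect_equal(as.numeric(r$X), c(2 / 3, 1 / 3))
  expect_error(restrict_channels(ds, 5L), "channels")
})

test_that("the one-against-one SVM separates simple point clouds", {
  X <- rbind(matrix(rnorm(8, mean = 0, sd = 0.1), 4),
             matrix(rnorm(8, mean = 3, sd = 0.1), 4))
  y <- factor(rep(c("rest", "palmar"), each = 4),
              levels = c("rest", "palmar"))
  m <- train_classifier(X, y)
  expect_equal(mean(predict_classes(m, X) == y), 1)
  # training point re-presented keeps its label
  expect_equal(as.character(predict_classes(m, X[1, , drop = FALSE])),
               "rest")
  # contradictory duplicate labels are unrealizable
  Xc <- rbind(X, X[1, ])
  yc <- factor(c(as.character(y), "palmar"), levels = levels(y))
  mc <- train_classifier(Xc, yc)
  expect_lt(mean(predict_classes(mc, Xc) == yc), 1)
  # degenerate inputs
  expect_error(train_classifier(X, factor(rep("rest", 8))), "2 classes")
  expect_identical(length(predict_classes(m, X[0, , drop = FALSE])), 0L)
  expect_error(predict_classes(m, X[, 1, drop = FALSE]), "dimension")
})

test_that("with two classes the ensemble is exactly one binary SVM", {
  withr::with_seed(31, {
    X <- rbind(matrix(rnorm(40, 0, 1), 20), matrix(rnorm(40, 1.5, 1), 20))
  })
  y <- factor(rep(c("rest", "pinch"), each = 20), levels = c("rest", "pinch"))
  cfg <- svm_config(cost = 5, gamma = 0.5)
  m <- train_classifier(X, y, cfg)
  single <- e1071::svm(x = X, y = y, kernel = "radial", cost = 5,
                       gamma = 0.5, scale = FALSE)
  expect_identical(as.character(predict_classes(m, X)),
                   as.character(predict(single, X)))
})

test_that("leave-one-out validation reports coherent ratios", {
  withr::with_seed(13, {
    centers <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4), 4, byrow = TRUE)
    X <- do.call(rbind, lapply(1:4, function(k)
      sweep(matrix(rnorm(20, sd = 0.3), 10, 2), 2, centers[k, ], `+`)))
  })
  y <- factor(rep(grip_classes(), each = 10), levels = grip_classes())
  res <- loo_validate(X, y)
  expect_equal(res$rr, 1)
  expect_equal(res$rr, sum(diag(res$confusion)) / length(y))
  expect_equal(sum(res$confusion), length(y))
  # label permutation collapses to chance
  withr::with_seed(14, {
    rrs <- replicate(10, loo_validate(X, sample(y))$rr)
  })
  expect_gt(mean(rrs), 0.05)
  expect_lt(mean(rrs), 0.45)
  # precondition: more epochs than classes
  four <- c(1, 11, 21, 31)
  expect_error(loo_validate(X[four, ], y[four]), "epoch")
})

test_that("inner grid-search tuning stays on the training fold and works", {
  withr::with_seed(15, {
    X <- rbind(matrix(rnorm(40, 0, 0.4), 20), matrix(rnorm(40, 2, 0.4), 20))
  })
  y <- factor(rep(c("rest", "little"), each = 20),
              levels = c("rest", "little"))
  cfg <- svm_config(tune = TRUE, cost_grid = c(1, 10), gamma_grid = c(0.1, 1))
  m <- train_classifier(X, y, cfg)
  expect_equal(mean(predict_classes(m, X) == y), 1)
})
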