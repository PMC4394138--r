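test_that("the normalization template gives mean 0 / sd 1 on training data only", {
  set.seed(5)
  x <- matrix(rnorm(600, mean = 3, sd = 2), ncol = 6)
  colnames(x) <- paste0("f", 1:6)
  tmpl <- fit_normalizer(x)
  xn <- apply_normalizer(tmpl, x)
  expect_lt(max(abs(colMeans(xn))), 1e-9)
  expect_lt(max(abs(apply(xn, 2, sd) - 1)), 1e-9)
  # the frozen template applied to a shifted set does not re-center it
  y <- x + 5
  yn <- apply_normalizer(tmpl, y)
  expect_gt(min(abs(colMeans(yn))), 1)
})

test_that("zero-variance features are flagged, clamped and warned about", {
  x <- cbind(a = rnorm(50), b = rep(2, 50))
  expect_warning(tmpl <- fit_normalizer(x), "zero-variance")
  expect_true(tmpl$flagged[["b"]])
  xn <- apply_normalizer(tmpl, x)
  expect_true(all(xn[, "b"] == 0))
})

# two-feature blobs: class 1 shifted by `sep` along both features
blob_features <- function(n, sep, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0, 1), each = n)
  x <- matrix(rnorm(4 * n), ncol = 2) + sep * labels
  colnames(x) <- c("f1", "f2")
  list(x = x, labels = labels)
}

test_that("linearly separable classes give training AUC 1", {
  d <- blob_features(100, sep = 8)
  model <- train_seizure_model(d$x, d$labels, seed = 3)
  fm <- make_feature_matrix(
    array(d$x, dim = c(nrow(d$x), 1, 2)), c("f1", "f2"))
  tr <- predict_probabilities(model, fm, smoothing_window = 1)
  expect_equal(oracle_rank_auc(tr$fused, d$labels), 1)
})

test_that("permuted labels give chance-level held-out AUC", {
  d <- blob_features(200, sep = 3, seed = 11)
  set.seed(21)
  perm <- sample(d$labels)            # break any label-feature association
  train_idx <- sample(length(perm), 200)
  model <- train_seizure_model(d$x[train_idx, ], perm[train_idx], seed = 21)
  fm <- make_feature_matrix(
    array(d$x[-train_idx, ], dim = c(200, 1, 2)), c("f1", "f2"))
  tr <- predict_probabilities(model, fm, smoothing_window = 1)
  auc <- oracle_rank_auc(tr$fused, perm[-train_idx])
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("single-class training data is rejected", {
  d <- blob_features(20, sep = 1)
  expect_error(train_seizure_model(d$x, rep(0, nrow(d$x))), "both")
})

test_that("moving average matches direct arithmetic and its fixed points", {
  x <- rep(0.3, 50)
  expect_equal(moving_average(x, 15), x)
  set.seed(6)
  y <- runif(80)
  expect_equal(moving_average(y, 1), y)
  for (w in c(3, 7, 15)) {
    expect_equal(moving_average(y, w), oracle_moving_average(y, w),
                 tolerance = 1e-12)
  }
  spike <- c(rep(0, 30), 1, rep(0, 30))
  sm <- moving_average(spike, 15)
  expect_equal(max(sm), 1 / 15)
  expect_equal(sum(sm > 0), 15)
})

test_that("prediction checks the feature registry fingerprint", {
  d <- blob_features(50, sep = 5)
  model <- train_seizure_model(d$x, d$labels, seed = 1)
  fm <- make_feature_matrix(array(rnorm(20), dim = c(10, 1, 2)),
                            c("other1", "other2"))
  expect_error(predict_probabilities(model, fm), "fingerprint")
})

test_that("binarize applies threshold, collar and run merging", {
  # epoch timestamps 4, 8, ..., with one supra-threshold epoch at t = 100 s
  p <- rep(0.1, 60)
  p[which(4 * seq_len(60) == 100)] <- 0.9
  tr <- make_trace(matrix(p, nrow = 1))
  dec <- binarize(tr, theta = 0.5, collar_s = 8)
  expect_equal(dec$events$onset_s, 92)
  expect_equal(dec$events$offset_s, 112)
  # collar 0: events are exactly the supra-threshold runs
  dec0 <- binarize(tr, theta = 0.5, collar_s = 0)
  expect_equal(dec0$events$onset_s, 100)
  expect_equal(dec0$events$offset_s, 104)
  # all sub-threshold: no events
  dec_none <- binarize(make_trace(matrix(rep(0.2, 30), 1)), 0.5, 32)
  expect_equal(nrow(dec_none$events), 0)
  # two nearby runs merged by the collar
  p2 <- rep(0, 40); p2[c(10, 13)] <- 1
  d2 <- binarize(make_trace(matrix(p2, 1)), 0.5, collar_s = 8)
  expect_equal(nrow(d2$events), 1)
})

test_that("raising the threshold never adds detected epochs; collars nest", {
  set.seed(8)
  for (rep_i in 1:20) {
    p <- runif(50)
    tr <- make_trace(matrix(p, nrow = 1))
    th <- sort(runif(2))
    d_lo <- binarize(tr, th[1], 0)
    d_hi <- binarize(tr, th[2], 0)
    expect_true(all(d_hi$binary <= d_lo$binary))
    c2 <- binarize(tr, 0.5, 16)
    c1 <- binarize(tr, 0.5, 4)
    # every second detected under the small collar is detected under the big
    grid <- seq(0, 200, by = 1)
    in1 <- overlaps_any_events(grid, grid + 1, c1$events)
    in2 <- overlaps_any_events(grid, grid + 1, c2$events)
    expect_true(all(in2[in1]))
  }
})

test_that("the fused trace is invariant under channel permutation", {
  set.seed(12)
  m <- matrix(runif(5 * 40), nrow = 5)
  tr1 <- make_trace(m)
  tr2 <- make_trace(m[c(3, 1, 5, 2, 4), ])
  expect_equal(tr1$fused, tr2$fused)
})

test_that("probability traces validate their range and fuse by max", {
  expect_error(make_trace(matrix(c(0.5, 1.2), 1)), "\\[0, 1\\]")
  m <- matrix(c(0.1, 0.9, 0.4, 0.2), nrow = 2)
  tr <- make_trace(m)
  expect_equal(tr$fused, c(0.9, 0.4))
})
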