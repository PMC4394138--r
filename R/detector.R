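#' Fit an anisotropic normalization template
#'
#' Estimates per-feature mean and standard deviation on training rows;
#' applying the template subtracts the mean and divides by the standard
#' deviation so every feature is commensurable. The template is frozen at
#' training time and re-applied unchanged to test data. Zero-variance
#' features are flagged, their standard deviation clamped to 1 (so the
#' transformed column is all zeros), and a warning is emitted.
#'
#' @param x A numeric matrix (rows = feature vectors) or a `feature_matrix`.
#' @return A `normalizer_template` with `mean`, `sd`, `flagged`.
#' @export
fit_normalizer <- function(x) {
  if (inherits(x, "feature_matrix")) x <- feature_rows(x)$matrix
  stopifnot(is.matrix(x), nrow(x) >= 2)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  flagged <- !is.finite(sd_) | sd_ <= 0
  if (any(flagged)) {
    warning(sum(flagged), " zero-variance feature(s) flagged; sd clamped to 1",
            call. = FALSE)
    sd_[flagged] <- 1
  }
  structure(
    list(mean = mu, sd = sd_, flagged = flagged,
         feature_names = colnames(x)),
    class = "normalizer_template"
  )
}

#' Apply a normalization template
#' @param template A `normalizer_template` from [fit_normalizer()].
#' @param x Numeric matrix with the same columns as the training data.
#' @return The normalized matrix.
#' @export
apply_normalizer <- function(template, x) {
  stopifnot(inherits(template, "normalizer_template"),
            ncol(x) == length(template$mean))
  sweep(sweep(x, 2, template$mean, "-"), 2, template$sd, "/")
}

#' Train the probabilistic seizure classifier
#'
#' Fits the normalization template on the training feature rows, then a
#' Gaussian-kernel support vector machine with sigmoid (Platt) probability
#' calibration on the normalized rows. The sigmoid is fitted on internal
#' cross-validated decision values, so the reported probabilities are not
#' optimistically calibrated on training scores. Class imbalance is handled
#' by inverse-frequency class weights.
#'
#' @param features A `feature_matrix` (all channels pooled) or a plain
#'   numeric matrix of feature rows.
#' @param labels Logical/0-1 vector, one per feature row (channel-epoch),
#'   `TRUE`/1 = seizure. For a `feature_matrix` the row order is the one
#'   produced by pooling channels (epoch index fastest); use
#'   [label_feature_rows()] to build it from annotations.
#' @param cost SVM regularization constant (default 1).
#' @param gamma RBF kernel width (default `1/n_features`).
#' @param max_train_rows Optional cap on training rows; when exceeded, rows
#'   are subsampled preserving the class mix (keeps training desk-scale).
#' @param seed Integer seed (sigmoid calibration folds and subsampling).
#' @return A `seizure_model` bundling the SVM, the frozen normalizer and
#'   the feature-name fingerprint.
#' @export
train_seizure_model <- function(features, labels, cost = 1, gamma = NULL,
                                max_train_rows = 4000, seed = 1L) {
  x <- if (inherits(features, "feature_matrix")) {
    feature_rows(features)$matrix
  } else features
  labels <- as.integer(as.logical(labels))
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("training data must contain both seizure and non-seizure epochs",
         call. = FALSE)
  }
  set.seed(seed)
  if (!is.null(max_train_rows) && nrow(x) > max_train_rows) {
    keep <- unlist(lapply(split(seq_len(nrow(x)), labels), function(idx) {
      n_keep <- max(2, round(max_train_rows * length(idx) / nrow(x)))
      sample(idx, min(length(idx), n_keep))
    }))
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  template <- fit_normalizer(x)
  xn <- apply_normalizer(template, x)
  if (is.null(gamma)) gamma <- 1 / ncol(xn)
  wts <- length(labels) / (2 * table(factor(labels, levels = c(0, 1))))
  fit <- e1071::svm(
    x = xn, y = factor(labels, levels = c(0, 1)),
    kernel = "radial", cost = cost, gamma = gamma,
    class.weights = stats::setNames(as.numeric(wts), c("0", "1")),
    probability = TRUE, scale = FALSE
  )
  structure(
    list(
      svm = fit,
      normalizer = template,
      feature_names = colnames(x),
      config = list(cost = cost, gamma = gamma, seed = seed)
    ),
    class = "seizure_model"
  )
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf(
    "<seizure_model> RBF SVM, %d support vectors, %d features, cost %g, gamma %g\n",
    x$svm$tot.nSV, length(x$feature_names), x$config$cost, x$config$gamma))
  invisible(x)
}

# raw (unsmoothed) per-row seizure probabilities from the calibrated SVM
svm_probabilities <- function(model, x) {
  xn <- apply_normalizer(model$normalizer, x)
  pred <- stats::predict(model$svm, xn, probability = TRUE)
  attr(pred, "probabilities")[, "1"]
}

#' Centered moving average with shrinking edge windows
#'
#' At interior points this is the mean over a centered window of
#' `window` values; near the edges the window shrinks symmetrically-clipped
#' to the available samples, so no padding bias is introduced.
#'
#' @param x Numeric vector.
#' @param window Odd window length in samples (window = 1 is the identity).
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  n <- length(x)
  half <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-channel probabilities, smoothing and max-fusion
#'
#' Applies the calibrated classifier separately to each channel of a
#' feature matrix (neonatal seizures can be localized to a single
#' channel), smooths each channel's probability trace time-wise with a
#' centered moving-average filter, and fuses the smoothed traces by taking
#' the per-timepoint maximum across channels — the final probability of
#' the system. Epochs are timestamped hop-aligned at epoch start + 4 s.
#'
#' @param model A `seizure_model`.
#' @param features A `feature_matrix` whose feature names match the model
#'   fingerprint.
#' @param smoothing_window Moving-average length in epochs (default 15,
#'   i.e. 60 s at the 4 s hop).
#' @return A `probability_trace`: list with `per_channel` (channels x
#'   epochs matrix of smoothed probabilities), `fused`, `times_s`,
#'   `channel_labels`, `smoothing_window`, `hop_s`.
#' @export
predict_probabilities <- function(model, features, smoothing_window = 15) {
  stopifnot(inherits(model, "seizure_model"),
            inherits(features, "feature_matrix"))
  if (!identical(model$feature_names, features$feature_names)) {
    stop("feature registry fingerprint does not match the model",
         call. = FALSE)
  }
  d <- dim(features$values)
  per_channel <- matrix(0, nrow = d[2], ncol = d[1])
  for (ch in seq_len(d[2])) {
    p_raw <- svm_probabilities(model, features$values[, ch, , drop = TRUE])
    per_channel[ch, ] <- moving_average(p_raw, smoothing_window)
  }
  rownames(per_channel) <- features$channel_labels
  probability_trace(per_channel,
                    times_s = features$epoch_start_s + features$hop_s,
                    smoothing_window = smoothing_window,
                    hop_s = features$hop_s)
}

#' Construct a probability trace
#'
#' The fused trace is always the per-timepoint maximum of the per-channel
#' (already smoothed) probabilities.
#'
#' @param per_channel Channels x epochs matrix of probabilities in `[0,1]`.
#' @param times_s Epoch timestamps in seconds (hop-aligned).
#' @param smoothing_window Smoothing window (epochs) used to produce
#'   `per_channel`; metadata only.
#' @param hop_s Epoch hop in seconds (default 4).
#' @return A `probability_trace`.
#' @export
probability_trace <- function(per_channel, times_s,
                              smoothing_window = 15, hop_s = 4) {
  per_channel <- as.matrix(per_channel)
  stopifnot(ncol(per_channel) == length(times_s))
  if (any(per_channel < 0 | per_channel > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  fused <- apply(per_channel, 2, max)
  structure(
    list(
      per_channel = per_channel,
      fused = fused,
      times_s = times_s,
      channel_labels = rownames(per_channel) %||%
        paste0("ch", seq_len(nrow(per_channel))),
      smoothing_window = smoothing_window,
      hop_s = hop_s
    ),
    class = "probability_trace"
  )
}

#' @export
print.probability_trace <- function(x, ...) {
  cat(sprintf(
    "<probability_trace> %d channels x %d epochs, fused max %.3f\n",
    nrow(x$per_channel), ncol(x$per_channel), max(x$fused)))
  invisible(x)
}

#' Threshold the fused probability and apply the collar
#'
#' The fused trace is compared with threshold `theta`: epochs with
#' probability >= theta are seizure (1). Each maximal run of 1s becomes an
#' event covering its epochs' `[time, time + hop)` intervals; every event
#' is then extended by `collar_s` seconds on both sides (compensating the
#' moving-average delay and onset/offset uncertainty), clipped to the
#' record bounds, and touching events are merged.
#'
#' @param trace A `probability_trace`.
#' @param theta Decision threshold in `[0, 1]` (default 0.5, the value
#'   fixed for clinical use).
#' @param collar_s Collar length in seconds per side (default 32).
#' @return A `decision_trace`: list with `binary` (pre-collar 0/1 per
#'   epoch), `events` (post-collar [annotation_track()]), `theta`,
#'   `collar_s`, `times_s`, `hop_s`.
#' @export
binarize <- function(trace, theta = 0.5, collar_s = 32) {
  stopifnot(inherits(trace, "probability_trace"),
            theta >= 0, theta <= 1, collar_s >= 0)
  binary <- as.integer(trace$fused >= theta)
  hop <- trace$hop_s
  lo <- trace$times_s[1]
  hi <- trace$times_s[length(trace$times_s)] + hop
  r <- rle(binary)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- starts[r$values == 1]
  off <- ends[r$values == 1]
  events <- if (length(on) == 0) annotation_track() else {
    o <- pmax(trace$times_s[on] - collar_s, lo)
    f <- pmin(trace$times_s[off] + hop + collar_s, hi)
    merge_intervals(o, f)
  }
  structure(
    list(binary = binary, events = events, theta = theta,
         collar_s = collar_s, times_s = trace$times_s, hop_s = hop),
    class = "decision_trace"
  )
}

#' @export
print.decision_trace <- function(x, ...) {
  cat(sprintf(
    "<decision_trace> theta %.2f, collar %g s: %d epoch(s) supra-threshold, %d event(s)\n",
    x$theta, x$collar_s, sum(x$binary), nrow(x$events)))
  invisible(x)
}

#' Label pooled feature rows from annotations
#'
#' Builds the 0/1 training-label vector matching the row order of pooled
#' feature matrices: an epoch-channel row is labelled seizure when the
#' epoch's hop interval `[time, time + hop)` overlaps an annotated event
#' on that channel.
#'
#' @param features A `feature_matrix`.
#' @param channel_annotations Either a single [annotation_track()] applied
#'   to all channels, or a list of one track per channel (per-channel
#'   ground truth, as returned by [simulate_recording()]).
#' @return Integer vector of 0/1 labels.
#' @export
label_feature_rows <- function(features, channel_annotations) {
  d <- dim(features$values)
  t0 <- features$epoch_start_s + features$hop_s
  t1 <- t0 + features$hop_s
  per_channel <- if (inherits(channel_annotations, "annotation_track")) {
    rep(list(channel_annotations), d[2])
  } else channel_annotations
  stopifnot(length(per_channel) == d[2])
  labs <- integer(0)
  for (ch in seq_len(d[2])) {
    labs <- c(labs, as.integer(overlaps_any(t0, t1, per_channel[[ch]])))
  }
  labs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
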