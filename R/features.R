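#' The default 55-feature registry
#'
#' The classifier consumes a 55-dimensional feature vector per epoch and
#' channel, spanning time-domain, frequency-domain and information-theory
#' descriptors of the 8 s, 32 Hz epoch. The registry is data: a tibble of
#' (name, category) rows whose order fixes the feature-vector order used by
#' the normalizer and the classifier. A subset or reordering can be passed
#' to [extract_features()] to swap in an alternative feature set without
#' code changes.
#'
#' Time domain (12): RMS amplitude, mean absolute amplitude, peak-to-peak,
#' line length, zero crossings, Hjorth activity/mobility/complexity,
#' skewness, kurtosis, mean nonlinear (Teager) energy, RMS of the first
#' difference. Frequency domain (32): total 0.5-12.8 Hz power, 12 absolute
#' and 12 relative band powers on a 1 Hz comb (0.5-1, 1-2, ..., 11-12 Hz),
#' peak frequency, spectral centroid and bandwidth, spectral
#' edge frequencies (80/90/95%), spectral slope. Information theory (11):
#' amplitude-histogram Shannon entropy, normalized spectral entropy, SVD
#' (embedding) entropy, and autoregressive prediction-error variance at
#' model orders 1-8.
#'
#' @return A tibble of class `feature_registry` with columns `name`,
#'   `category`.
#' @export
feature_registry <- function() {
  bands <- sprintf("bp_%s", c("0.5_1", paste(1:11, 2:12, sep = "_")))
  entries <- rbind(
    data.frame(name = c(
      "rms_amplitude", "mean_abs_amplitude", "peak_to_peak", "line_length",
      "zero_crossings", "hjorth_activity", "hjorth_mobility",
      "hjorth_complexity", "skewness", "kurtosis", "nonlinear_energy",
      "rms_first_diff"
    ), category = "time"),
    data.frame(name = c(
      "total_power", bands, paste0("rel_", bands),
      "peak_frequency", "spectral_centroid",
      "spectral_bandwidth", "sef80", "sef90", "sef95", "spectral_slope"
    ), category = "frequency"),
    data.frame(name = c(
      "amplitude_entropy", "spectral_entropy", "svd_entropy",
      paste0("ar_error_", 1:8)
    ), category = "information")
  )
  out <- tibble::as_tibble(entries)
  class(out) <- c("feature_registry", class(out))
  out
}

# Welch PSD: 128-sample Hann segments, 50% overlap, one-sided density.
# Returns freq grid (Hz) and density such that sum(psd * df) = signal power.
welch_psd <- function(x, fs, seg_len = 128) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- seg_len %/% 2
  starts <- seq(1, n - seg_len + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  u <- sum(w^2)
  acc <- numeric(seg_len %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[1:(seg_len %/% 2 + 1)]
  }
  psd <- acc / (length(starts) * u * fs)
  psd[2:(seg_len %/% 2)] <- 2 * psd[2:(seg_len %/% 2)]
  list(freq = seq(0, seg_len %/% 2) * fs / seg_len, psd = psd,
       df = fs / seg_len)
}

# prediction-error variances for AR orders 1..max_order (Levinson-Durbin)
ar_prediction_errors <- function(x, max_order = 8) {
  n <- length(x)
  r <- stats::acf(x, lag.max = max_order, type = "covariance",
                  plot = FALSE, demean = TRUE)$acf[, 1, 1]
  err <- numeric(max_order)
  e <- r[1]
  a <- numeric(0)
  for (m in seq_len(max_order)) {
    k <- (r[m + 1] - sum(a * r[m:2][seq_len(m - 1)])) / e
    if (m == 1) k <- r[2] / e
    a_new <- c(a - k * rev(a), k)
    e <- e * (1 - k^2)
    a <- a_new
    err[m] <- e
  }
  err
}

# spectral edge frequency: smallest f below which `frac` of band power lies
spectral_edge <- function(freq, psd, frac) {
  cum <- cumsum(psd)
  tot <- cum[length(cum)]
  if (tot <= 0) return(0)
  freq[which(cum >= frac * tot)[1]]
}

# all 55 features of one epoch vector; degenerate (zero-variance) epochs map
# to the documented sentinel conventions (entropy/mobility/edge features 0)
epoch_features <- function(x, fs) {
  n <- length(x)
  out <- numeric(0)
  v <- stats::var(x) * (n - 1) / n
  degenerate <- v < .Machine$double.eps

  # --- time domain ---
  d1 <- diff(x)
  d2 <- diff(d1)
  mob <- if (degenerate) 0 else sqrt((stats::var(d1) * (n - 2) / (n - 1)) / v)
  mob_d <- if (stats::var(d1) < .Machine$double.eps) 0 else
    sqrt(stats::var(d2) / stats::var(d1))
  xm <- x - mean(x)
  sk <- if (degenerate) 0 else mean(xm^3) / (sqrt(v)^3)
  ku <- if (degenerate) 0 else mean(xm^4) / v^2
  nle <- mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
  out <- c(out,
    rms_amplitude = sqrt(mean(x^2)),
    mean_abs_amplitude = mean(abs(x)),
    peak_to_peak = max(x) - min(x),
    line_length = sum(abs(d1)),
    zero_crossings = sum(diff(sign(xm)[sign(xm) != 0]) != 0),
    hjorth_activity = v,
    hjorth_mobility = mob,
    hjorth_complexity = if (mob == 0) 0 else mob_d / mob,
    skewness = sk,
    kurtosis = ku,
    nonlinear_energy = nle,
    rms_first_diff = sqrt(mean(d1^2))
  )

  # --- frequency domain (0.5-12.8 Hz analysis band) ---
  W <- welch_psd(x, fs)
  band <- W$freq >= 0.5 & W$freq <= 12.8
  fb <- W$freq[band]; pb <- W$psd[band]
  total <- sum(pb) * W$df
  band_edges <- cbind(c(0.5, 1:11), c(1, 2:12))
  bp <- vapply(seq_len(nrow(band_edges)), function(i) {
    sel <- fb >= band_edges[i, 1] & fb < band_edges[i, 2]
    sum(pb[sel]) * W$df
  }, numeric(1))
  rel <- if (total > 0) bp / total else rep(0, length(bp))
  pk <- if (degenerate || total <= 0) c(0, 0) else {
    i <- which.max(pb); c(fb[i], pb[i])
  }
  centroid <- if (total > 0) sum(fb * pb) / sum(pb) else 0
  bw <- if (total > 0) sqrt(sum((fb - centroid)^2 * pb) / sum(pb)) else 0
  slope <- if (degenerate || total <= 0) 0 else {
    sel <- fb >= 1 & pb > 0
    lf <- log10(fb[sel]); lp <- log10(pb[sel])
    stats::cov(lf, lp) / stats::var(lf)
  }
  bands_names <- sprintf("bp_%s", c("0.5_1", paste(1:11, 2:12, sep = "_")))
  names(bp) <- bands_names
  names(rel) <- paste0("rel_", bands_names)
  out <- c(out,
    total_power = total, bp, rel,
    peak_frequency = pk[1], peak_power = pk[2],
    spectral_centroid = centroid, spectral_bandwidth = bw,
    sef80 = if (degenerate) 0 else spectral_edge(fb, pb, 0.80),
    sef90 = if (degenerate) 0 else spectral_edge(fb, pb, 0.90),
    sef95 = if (degenerate) 0 else spectral_edge(fb, pb, 0.95),
    spectral_slope = slope
  )

  # --- information theory ---
  amp_ent <- if (degenerate) 0 else {
    h <- graphics::hist(x, breaks = 16, plot = FALSE)$counts
    p <- h[h > 0] / sum(h)
    -sum(p * log(p)) / log(16)
  }
  spec_ent <- if (degenerate || total <= 0) 0 else {
    p <- pb[pb > 0] / sum(pb[pb > 0])
    -sum(p * log(p)) / log(length(pb))
  }
  svd_ent <- if (degenerate) 0 else {
    emb_dim <- 10
    m <- stats::embed(x, emb_dim)
    sv <- svd(m, nu = 0, nv = 0)$d
    p <- sv[sv > 0] / sum(sv)
    -sum(p * log(p)) / log(emb_dim)
  }
  ar_err <- if (degenerate) rep(0, 8) else ar_prediction_errors(x, 8)
  names(ar_err) <- paste0("ar_error_", 1:8)
  out <- c(out,
    amplitude_entropy = amp_ent,
    spectral_entropy = spec_ent,
    svd_entropy = svd_ent,
    ar_err
  )
  out[!is.finite(out)] <- 0
  out
}

#' Extract the per-epoch, per-channel feature matrix
#'
#' Computes every registry feature on each (epoch, channel) signal of an
#' epoch tensor. All values are finite: degenerate (flat) epochs produce
#' the documented sentinel value 0 for entropy-, mobility- and edge-type
#' features.
#'
#' @param epochs An `epoch_tensor` from [make_epochs()].
#' @param registry A [feature_registry()] (or a subset/reordering of it).
#' @return A `feature_matrix`: list with `values` (epochs x channels x
#'   n_features array), `feature_names`, `epoch_start_s`, `channel_labels`.
#' @export
extract_features <- function(epochs, registry = feature_registry()) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  d <- dim(epochs$values)
  full <- feature_registry()
  unknown <- setdiff(registry$name, full$name)
  if (length(unknown) > 0) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- array(0, dim = c(d[1], d[2], nrow(registry)))
  for (k in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      f <- epoch_features(epochs$values[k, ch, ], epochs$sample_rate_hz)
      vals[k, ch, ] <- f[registry$name]
    }
  }
  structure(
    list(
      values = vals,
      feature_names = registry$name,
      epoch_start_s = epochs$epoch_start_s,
      hop_s = epochs$hop_s,
      length_s = epochs$length_s,
      channel_labels = epochs$channel_labels
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_matrix> %d epochs x %d channels x %d features\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# flatten a feature_matrix to rows = (epoch, channel) vectors, plus an index
feature_rows <- function(fm) {
  d <- dim(fm$values)
  m <- matrix(0, nrow = d[1] * d[2], ncol = d[3])
  idx <- expand.grid(epoch = seq_len(d[1]), channel = seq_len(d[2]))
  for (ch in seq_len(d[2])) {
    rows <- (ch - 1) * d[1] + seq_len(d[1])
    m[rows, ] <- fm$values[, ch, ]
  }
  colnames(m) <- fm$feature_names
  # rows ordered channel-major: epoch index recycles fastest
  list(matrix = m, epoch = idx$epoch, channel = idx$channel)
}
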