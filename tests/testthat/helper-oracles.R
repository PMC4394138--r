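# independent brute-force oracles used to cross-check the implementation

# epoch confusion by literal per-epoch interval enumeration
oracle_epoch_confusion <- function(det_events, truth_events, duration_s,
                                   hop = 4) {
  n <- floor(duration_s / hop)
  in_any <- function(a, b, ev) {
    if (nrow(ev) == 0) return(FALSE)
    hit <- FALSE
    for (k in seq_len(nrow(ev))) {
      if (a < ev$offset_s[k] && b > ev$onset_s[k]) hit <- TRUE
    }
    hit
  }
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(n)) {
    a <- (i - 1) * hop; b <- a + hop
    t_pos <- in_any(a, b, truth_events)
    d_pos <- in_any(a, b, det_events)
    if (t_pos && d_pos) tp <- tp + 1
    if (t_pos && !d_pos) fn <- fn + 1
    if (!t_pos && d_pos) fp <- fp + 1
    if (!t_pos && !d_pos) tn <- tn + 1
  }
  list(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  )
}

# event metrics by literal double loop over event pairs
oracle_event_metrics <- function(det_events, truth_events, duration_s) {
  overlap <- function(a1, b1, a2, b2) a1 < b2 && b1 > a2
  detected <- 0
  if (nrow(truth_events) > 0) {
    for (i in seq_len(nrow(truth_events))) {
      hit <- FALSE
      if (nrow(det_events) > 0) {
        for (j in seq_len(nrow(det_events))) {
          if (overlap(truth_events$onset_s[i], truth_events$offset_s[i],
                      det_events$onset_s[j], det_events$offset_s[j])) {
            hit <- TRUE
          }
        }
      }
      if (hit) detected <- detected + 1
    }
  }
  n_false <- 0
  if (nrow(det_events) > 0) {
    for (j in seq_len(nrow(det_events))) {
      hit <- FALSE
      if (nrow(truth_events) > 0) {
        for (i in seq_len(nrow(truth_events))) {
          if (overlap(truth_events$onset_s[i], truth_events$offset_s[i],
                      det_events$onset_s[j], det_events$offset_s[j])) {
            hit <- TRUE
          }
        }
      }
      if (!hit) n_false <- n_false + 1
    }
  }
  list(
    gdr = if (nrow(truth_events) == 0) NA_real_
          else 100 * detected / nrow(truth_events),
    fd_per_hour = n_false / (duration_s / 3600)
  )
}

# trapezoid AUC written out point by point, with forced endpoints
oracle_trapezoid <- function(se, sp, endpoints = TRUE) {
  if (endpoints) { se <- c(1, se, 0); sp <- c(0, sp, 1) }
  ord <- order(sp, -se)
  se <- se[ord]; sp <- sp[ord]
  total <- 0
  for (i in 2:length(sp)) {
    total <- total + (sp[i] - sp[i - 1]) * (se[i] + se[i - 1]) / 2
  }
  total
}

# centered moving average by direct windowed mean
oracle_moving_average <- function(x, w) {
  half <- (w - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)])
  }, numeric(1))
}

# Wilcoxon/Mann-Whitney AUC of scores against binary labels
oracle_rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(r)
}

# does each query interval [a_i, b_i) overlap any event row?
overlaps_any_events <- function(a, b, ev) {
  vapply(seq_along(a), function(i) {
    nrow(ev) > 0 && any(a[i] < ev$offset_s & b[i] > ev$onset_s)
  }, logical(1))
}

# random non-overlapping event track on [0, duration]
random_events <- function(duration_s, max_events = 3) {
  k <- sample(0:max_events, 1)
  if (k == 0) return(annotation_track())
  bounds <- sort(stats::runif(2 * k, 0, duration_s))
  on <- bounds[seq(1, 2 * k, by = 2)]
  off <- bounds[seq(2, 2 * k, by = 2)]
  keep <- off - on > 1e-3
  if (!any(keep)) return(annotation_track())
  annotation_track(on[keep], off[keep])
}
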