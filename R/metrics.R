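#' Default decision-threshold grid
#' @return Thresholds 0.00 to 1.00 in steps of 0.01.
#' @export
default_threshold_grid <- function() seq(0, 1, by = 0.01)

# rasterize an annotation track onto the half-open hop grid covering
# [0, duration): TRUE where the epoch overlaps any event
rasterize_events <- function(events, duration_s, hop = 4) {
  n <- floor(duration_s / hop)
  t0 <- (seq_len(n) - 1) * hop
  overlaps_any(t0, t0 + hop, events)
}

#' Epoch-level confusion of decisions against ground truth
#'
#' Compares detector decisions with expert annotations epoch by epoch on
#' the 4 s hop grid: an epoch is positive when its half-open interval
#' overlaps an event. Sensitivity measures the temporal precision of
#' detected onsets/offsets (seizure burden); specificity the fraction of
#' non-seizure time left undetected. When a class is absent from the
#' truth, the corresponding metric is undefined and reported as `NA`.
#'
#' @param decisions A `decision_trace` (post-collar events are scored by
#'   default, on the trace's own epoch grid) or an [annotation_track()] of
#'   detected events (scored on the `[0, duration_s)` grid).
#' @param truth An [annotation_track()].
#' @param duration_s Record duration in seconds; only needed when
#'   `decisions` is an annotation track.
#' @param hop Epoch hop in seconds (default 4).
#' @param use_collar If `FALSE` and `decisions` is a `decision_trace`,
#'   score the pre-collar binary epochs instead of the collared events.
#' @return List with `sensitivity`, `specificity` and the confusion counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
epoch_confusion <- function(decisions, truth, duration_s = NULL, hop = 4,
                            use_collar = TRUE) {
  if (inherits(decisions, "decision_trace")) {
    t0 <- decisions$times_s
    hop <- decisions$hop_s
    truth_pos <- overlaps_any(t0, t0 + hop, truth)
    det_pos <- if (use_collar) {
      overlaps_any(t0, t0 + hop, decisions$events)
    } else {
      decisions$binary == 1
    }
  } else {
    if (is.null(duration_s)) {
      stop("duration_s is required for annotation-track decisions",
           call. = FALSE)
    }
    truth_pos <- rasterize_events(truth, duration_s, hop)
    det_pos <- rasterize_events(decisions, duration_s, hop)
  }
  tp <- sum(det_pos & truth_pos)
  fn <- sum(!det_pos & truth_pos)
  fp <- sum(det_pos & !truth_pos)
  tn <- sum(!det_pos & !truth_pos)
  list(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Event-level detection metrics
#'
#' A true seizure counts as detected when any detected event overlaps it
#' (any-overlap rule); a detected event is false when it overlaps no true
#' seizure. The good detection rate (GDR) is the percentage of true
#' seizures detected; the false detection rate is the number of false
#' events per hour of recording.
#'
#' @param decisions A `decision_trace` or an [annotation_track()] of
#'   detected events.
#' @param truth An [annotation_track()].
#' @param duration_s Record duration in seconds (> 0).
#' @return List with `gdr` (percent, `NA` when the record has no true
#'   seizures), `fd_per_hour`, `n_true`, `n_detected_true`, `n_false`.
#' @export
event_metrics <- function(decisions, truth, duration_s) {
  if (duration_s <= 0) stop("record duration must be positive", call. = FALSE)
  det <- if (inherits(decisions, "decision_trace")) decisions$events
         else decisions
  detected <- overlaps_any(truth$onset_s, truth$offset_s, det)
  false_ev <- !overlaps_any(det$onset_s, det$offset_s, truth)
  list(
    gdr = if (nrow(truth) == 0) NA_real_ else 100 * mean(detected),
    fd_per_hour = sum(false_ev) / (duration_s / 3600),
    n_true = nrow(truth),
    n_detected_true = sum(detected),
    n_false = sum(false_ev)
  )
}

#' Sensitivity/specificity matrices over a threshold grid
#'
#' For each patient and each threshold, thresholds the fused probability
#' trace and scores it epoch-wise against that patient's annotations,
#' producing the N x M sensitivity and specificity matrices from which
#' both AUC computation orders are derived. By default no collar is
#' applied, so SE is non-increasing and SP non-decreasing in the
#' threshold.
#'
#' @param traces List of `probability_trace`, one per patient.
#' @param truths List of [annotation_track()], same order.
#' @param durations_s Numeric vector of record durations.
#' @param thresholds Ascending threshold grid (default
#'   [default_threshold_grid()]).
#' @param collar_s Collar applied before scoring (default 0).
#' @return A `metrics_table`: list with `SE`, `SP` (thresholds x patients
#'   matrices of proportions), `thresholds`, `patients`, `level`.
#' @export
metrics_table <- function(traces, truths, durations_s,
                          thresholds = default_threshold_grid(),
                          collar_s = 0) {
  stopifnot(length(traces) == length(truths),
            length(traces) == length(durations_s),
            !is.unsorted(thresholds, strictly = TRUE), length(thresholds) >= 2)
  M <- length(traces)
  N <- length(thresholds)
  SE <- matrix(NA_real_, N, M)
  SP <- matrix(NA_real_, N, M)
  for (j in seq_len(M)) {
    for (i in seq_len(N)) {
      dec <- binarize(traces[[j]], thresholds[i], collar_s)
      cm <- epoch_confusion(dec, truths[[j]], durations_s[j],
                            hop = traces[[j]]$hop_s,
                            use_collar = collar_s > 0)
      SE[i, j] <- cm$sensitivity
      SP[i, j] <- cm$specificity
    }
  }
  structure(
    list(SE = SE, SP = SP, thresholds = thresholds,
         patients = names(traces) %||% paste0("patient", seq_len(M)),
         level = "epoch"),
    class = "metrics_table"
  )
}

# trapezoid AUC of one (SE, SP) threshold sweep; with endpoint
# augmentation the curve spans the full unit square (theta -> 0 gives
# SE 1 / SP 0, theta -> 1+ gives SE 0 / SP 1)
trapezoid_auc <- function(se, sp, endpoints = TRUE) {
  if (endpoints) {
    se <- c(1, se, 0)
    sp <- c(0, sp, 1)
  }
  ord <- order(sp, -se)
  se <- se[ord]; sp <- sp[ord]
  sum(diff(sp) * (se[-1] + se[-length(se)]) / 2)
}

check_complete <- function(table) {
  if (anyNA(table$SE) || anyNA(table$SP)) {
    stop("metrics table has missing sensitivity/specificity cells",
         call. = FALSE)
  }
}

#' AUC order 1: per-patient AUC, then average
#'
#' Computes the trapezoidal AUC of each patient's own
#' sensitivity/specificity sweep and averages across patients. This order
#' summarises the discriminability of the probabilistic output per
#' patient, and is the appropriate summary when the output is visualized
#' as a probability trace or colormap.
#'
#' @param table A `metrics_table` (complete, no missing cells).
#' @param endpoints Augment each curve with the (SE, SP) endpoints (1, 0)
#'   and (0, 1) so the trapezoid spans the unit square (default `TRUE`;
#'   `FALSE` reproduces the literal truncated-grid sums).
#' @return Mean per-patient AUC in `[0, 1]`.
#' @export
auc_per_patient_mean <- function(table, endpoints = TRUE) {
  stopifnot(inherits(table, "metrics_table"))
  check_complete(table)
  mean(vapply(seq_len(ncol(table$SE)), function(j) {
    trapezoid_auc(table$SE[, j], table$SP[, j], endpoints)
  }, numeric(1)))
}

#' AUC order 2: pool thresholds across patients, then AUC
#'
#' Averages sensitivity and specificity across patients at each threshold
#' first, then computes the trapezoidal AUC of the averaged curve. This
#' order summarises the performance achievable with one common threshold
#' for all patients — the appropriate summary when the output is
#' visualized in binary form. When patients' probability traces are
#' well-separated but differently calibrated, this AUC is strictly lower
#' than [auc_per_patient_mean()].
#'
#' @inheritParams auc_per_patient_mean
#' @return AUC of the patient-averaged curve in `[0, 1]`.
#' @export
auc_pooled_thresholds <- function(table, endpoints = TRUE) {
  stopifnot(inherits(table, "metrics_table"))
  check_complete(table)
  trapezoid_auc(rowMeans(table$SE), rowMeans(table$SP), endpoints)
}

#' Threshold-selection guide
#'
#' For every threshold on the grid, computes the mean good detection rate
#' across patients and the upper bound of the 95% confidence interval of
#' the mean number of false detections per hour (percentile bootstrap
#' across patients). Plotting mean GDR and the FD/h bound against the
#' threshold gives the over-pessimistic operating guide — regular benefit
#' at worst-case cost — used to fix the clinical threshold.
#'
#' @param traces List of `probability_trace`, one per patient.
#' @param truths List of [annotation_track()], same order.
#' @param durations_s Record durations in seconds.
#' @param thresholds Threshold grid (default [default_threshold_grid()]).
#' @param collar_s Collar applied to decisions (default 32).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param ci_method `"bootstrap"` (percentile, default) or `"normal"`
#'   (mean + 1.96 standard errors).
#' @return A tibble with columns `threshold`, `mean_gdr`,
#'   `mean_fd_per_hour`, `fd_per_hour_upper95` (`NA` with a single
#'   patient).
#' @export
threshold_guide <- function(traces, truths, durations_s,
                            thresholds = default_threshold_grid(),
                            collar_s = 32, n_boot = 2000, seed = 1L,
                            ci_method = c("bootstrap", "normal")) {
  ci_method <- match.arg(ci_method)
  M <- length(traces)
  set.seed(seed)
  boot_idx <- if (M >= 2) {
    matrix(sample.int(M, M * n_boot, replace = TRUE), nrow = n_boot)
  } else NULL
  rows <- lapply(thresholds, function(th) {
    gdr <- numeric(M); fdh <- numeric(M)
    for (j in seq_len(M)) {
      dec <- binarize(traces[[j]], th, collar_s)
      em <- event_metrics(dec, truths[[j]], durations_s[j])
      gdr[j] <- em$gdr
      fdh[j] <- em$fd_per_hour
    }
    upper <- if (M < 2) NA_real_ else if (ci_method == "bootstrap") {
      means <- rowMeans(matrix(fdh[boot_idx], nrow = n_boot))
      stats::quantile(means, 0.975, names = FALSE)
    } else {
      mean(fdh) + 1.96 * stats::sd(fdh) / sqrt(M)
    }
    tibble::tibble(
      threshold = th,
      mean_gdr = mean(gdr, na.rm = TRUE),
      mean_fd_per_hour = mean(fdh),
      fd_per_hour_upper95 = upper
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot the threshold-selection guide
#'
#' @param guide A tibble from [threshold_guide()].
#' @return A ggplot with mean GDR (%) and the FD/h 95% upper bound versus
#'   the threshold, on separate facets.
#' @export
plot_threshold_guide <- function(guide) {
  long <- tidyr::pivot_longer(
    guide[c("threshold", "mean_gdr", "fd_per_hour_upper95")],
    -"threshold", names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("mean_gdr", "fd_per_hour_upper95"),
                        labels = c("mean good detection rate (%)",
                                   "false detections / h (95% upper bound)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "decision threshold", y = NULL) +
    ggplot2::theme_minimal()
}
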