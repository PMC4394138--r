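#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a probability trace into long format
#'
#' @param x A `probability_trace`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `channel` (including
#'   `"fused"`), `probability`.
#' @export
tidy.probability_trace <- function(x, ...) {
  per <- tibble::tibble(
    time_s = rep(x$times_s, each = nrow(x$per_channel)),
    channel = rep(x$channel_labels, times = ncol(x$per_channel)),
    probability = as.vector(x$per_channel)
  )
  fused <- tibble::tibble(time_s = x$times_s, channel = "fused",
                          probability = x$fused)
  dplyr::bind_rows(per, fused)
}

#' Tidy a decision trace into its detected events
#' @param x A `decision_trace`.
#' @param ... Unused.
#' @return A tibble with `onset_s`, `offset_s`, `duration_s`.
#' @export
tidy.decision_trace <- function(x, ...) {
  tibble::tibble(
    onset_s = x$events$onset_s,
    offset_s = x$events$offset_s,
    duration_s = x$events$offset_s - x$events$onset_s
  )
}

#' One-row summary of a decision trace
#' @param x A `decision_trace`.
#' @param ... Unused.
#' @return A one-row tibble: `theta`, `collar_s`, `n_events`,
#'   `seizure_burden_s`.
#' @export
glance.decision_trace <- function(x, ...) {
  tibble::tibble(
    theta = x$theta, collar_s = x$collar_s, n_events = nrow(x$events),
    seizure_burden_s = sum(x$events$offset_s - x$events$onset_s)
  )
}

#' Tidy a metrics table into long format
#' @param x A `metrics_table`.
#' @param ... Unused.
#' @return A tibble with `threshold`, `patient`, `sensitivity`,
#'   `specificity`.
#' @export
tidy.metrics_table <- function(x, ...) {
  tibble::tibble(
    threshold = rep(x$thresholds, times = ncol(x$SE)),
    patient = rep(x$patients, each = nrow(x$SE)),
    sensitivity = as.vector(x$SE),
    specificity = as.vector(x$SP)
  )
}

#' One-row summary of a metrics table: both AUC orders
#' @param x A `metrics_table`.
#' @param ... Unused.
#' @return A one-row tibble with `auc_per_patient_mean` and
#'   `auc_pooled_thresholds`.
#' @export
glance.metrics_table <- function(x, ...) {
  tibble::tibble(
    auc_per_patient_mean = auc_per_patient_mean(x),
    auc_pooled_thresholds = auc_pooled_thresholds(x),
    n_thresholds = length(x$thresholds),
    n_patients = length(x$patients)
  )
}

#' One-row summary of a trained seizure model
#' @param x A `seizure_model`.
#' @param ... Unused.
#' @return A one-row tibble of hyperparameters and model size.
#' @export
glance.seizure_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_support_vectors = x$svm$tot.nSV,
    cost = x$config$cost,
    gamma = x$config$gamma
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods for detector outputs
#'
#' `autoplot()` dispatches to the display-layer plots:
#' probability traces to [plot_probability_trace()], decision traces to
#' [plot_binary_trace()], colormap grids to [plot_colormap()], aEEG
#' traces to [plot_aeeg()].
#'
#' @param object The result object.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot.
#' @name autoplot-neoseize
NULL

#' @rdname autoplot-neoseize
#' @export
autoplot.probability_trace <- function(object, ...) {
  plot_probability_trace(object, ...)
}

#' @rdname autoplot-neoseize
#' @export
autoplot.decision_trace <- function(object, ...) plot_binary_trace(object)

#' @rdname autoplot-neoseize
#' @export
autoplot.colormap_grid <- function(object, ...) plot_colormap(object)

#' @rdname autoplot-neoseize
#' @export
autoplot.aeeg_trace <- function(object, ...) plot_aeeg(object)
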