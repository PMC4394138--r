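#' Semilogarithmic aEEG display mapping
#'
#' The amplitude-integrated EEG display scale is linear from 0 to
#' 10 microvolts and logarithmic from 10 to 100 microvolts. The unique
#' continuous piecewise map with unit slope on the linear branch and one
#' decade (10-100) spanning the same display height is
#' `d(x) = x` for `x <= 10` and `d(x) = 10 * (1 + log10(x / 10))` above;
#' amplitudes beyond the 100 microvolt display ceiling are clipped
#' (display value 20).
#'
#' @param x Amplitude(s) in microvolts, `>= 0`.
#' @return Display-scale value(s): continuous, strictly increasing on
#'   `[0, 100]`, with `d(10) = 10` from both branches and `d(100) = 20`.
#' @export
aeeg_semilog <- function(x) {
  stopifnot(all(x >= 0))
  x <- pmin(x, 100)
  ifelse(x <= 10, x, 10 * (1 + log10(x / 10)))
}

#' Compute an amplitude-integrated EEG trace
#'
#' The classical bedside transform: band-pass filter the channel, rectify
#' (negative voltages become positive), smooth the rectified amplitude
#' with a moving-average filter, then record the maximum and minimum of
#' the smoothed amplitude over each display step. Both envelope borders
#' are also returned on the semilogarithmic display scale
#' ([aeeg_semilog()]). An increase of the lower border is the classical
#' aEEG signature of seizures.
#'
#' Filter passband (2-15 Hz), smoothing window (0.5 s) and display step
#' (15 s) follow standard aEEG practice and are configurable.
#'
#' @param rec An [eeg_recording()] (original or 32 Hz rate).
#' @param channel Channel label or index.
#' @param band Band-pass edges in Hz (default `c(2, 15)`).
#' @param smooth_s Moving-average window in seconds (default 0.5).
#' @param step_s Display step in seconds (default 15).
#' @return An `aeeg_trace` tibble with columns `time_s`, `lower_uv`,
#'   `upper_uv`, `lower_disp`, `upper_disp`.
#' @export
compute_aeeg <- function(rec, channel = 1, band = c(2, 15),
                         smooth_s = 0.5, step_s = 15) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- channel_data(rec, channel)
  fs <- rec$sample_rate_hz
  hi <- min(band[2], 0.45 * fs)                 # keep below Nyquist
  bf <- signal::butter(3, c(band[1], hi) / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, x)
  rectified <- abs(filtered)
  smoothed <- moving_average(rectified, max(1, round(smooth_s * fs)))
  step <- max(1, round(step_s * fs))
  n_steps <- max(1, floor(length(smoothed) / step))
  idx <- rep(seq_len(n_steps), each = step)[seq_len(n_steps * step)]
  seg <- smoothed[seq_len(n_steps * step)]
  lower <- tapply(seg, idx, min)
  upper <- tapply(seg, idx, max)
  out <- tibble::tibble(
    time_s = (seq_len(n_steps) - 1) * step_s,
    lower_uv = as.numeric(lower),
    upper_uv = as.numeric(upper),
    lower_disp = aeeg_semilog(as.numeric(lower)),
    upper_disp = aeeg_semilog(as.numeric(upper))
  )
  class(out) <- c("aeeg_trace", class(out))
  attr(out, "params") <- list(band = band, smooth_s = smooth_s,
                              step_s = step_s, channel = channel)
  out
}

#' Discrete probability bin for the spatio-temporal colormap
#'
#' Maps probabilities to the 10 colormap bins: `bin = min(floor(10 p), 9)`
#' (bins are right-open except the top one, so p = 0.5 falls in bin 5, the
#' first warm bin).
#'
#' @param p Probabilities in `[0, 1]`.
#' @return Integer bin indices in 0..9.
#' @export
probability_bin <- function(p) {
  if (any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pmin(floor(10 * p), 9)
}

#' The 10-colour diverging lookup table
#'
#' Cold blue (probability 0) through neutral white (0.5) to warm red (1).
#' @return Character vector of 10 colours, bin 0 first.
#' @export
colormap_colours <- function() {
  grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(10)
}

#' Build the spatio-temporal colormap grid
#'
#' Discretizes the per-channel probability traces into the 10-bin
#' channels x epochs grid displayed as the spatio-temporal colormap: both
#' the temporal and the spatial evolution of seizure support are visible
#' at once.
#'
#' @param trace A `probability_trace`.
#' @return A `colormap_grid`: list with `bins` (channels x epochs integer
#'   matrix in 0..9), `times_s`, `channel_labels`, `colours`, `edges`.
#' @export
build_colormap <- function(trace) {
  stopifnot(inherits(trace, "probability_trace"))
  bins <- probability_bin(trace$per_channel)
  structure(
    list(bins = bins, times_s = trace$times_s,
         channel_labels = trace$channel_labels,
         colours = colormap_colours(),
         edges = seq(0, 1, by = 0.1)),
    class = "colormap_grid"
  )
}

#' Colour segments of the fused probability trace
#'
#' Splits the fused trace into maximal runs below / at-or-above the
#' threshold; the trial display plots sub-threshold portions in blue and
#' supra-threshold portions in red.
#'
#' @param trace A `probability_trace`.
#' @param theta Decision threshold (default 0.5).
#' @return A tibble with one row per epoch: `time_s`, `probability`,
#'   `colour` ("blue"/"red") and `segment` (run id; the number of distinct
#'   values is the number of colour changes + 1).
#' @export
probability_trace_segments <- function(trace, theta = 0.5) {
  stopifnot(inherits(trace, "probability_trace"))
  above <- trace$fused >= theta
  seg <- cumsum(c(TRUE, diff(above) != 0))
  tibble::tibble(
    time_s = trace$times_s,
    probability = trace$fused,
    colour = ifelse(above, "red", "blue"),
    segment = seg
  )
}

#' Plot the fused probability trace with threshold colouring
#'
#' @param trace A `probability_trace`.
#' @param theta Decision threshold (default 0.5).
#' @return A ggplot: probability vs time (minutes), blue below the
#'   threshold, red at or above it.
#' @export
plot_probability_trace <- function(trace, theta = 0.5) {
  seg <- probability_trace_segments(trace, theta)
  # duplicate run boundaries so coloured line segments connect
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$time_s / 60,
                                    y = .data$probability,
                                    colour = .data$colour,
                                    group = .data$segment)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = theta, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (min)", y = "probability of seizure") +
    ggplot2::theme_minimal()
}

#' Plot the binary decision trace
#' @param decisions A `decision_trace`.
#' @return A ggplot step plot of the 0/1 decisions vs time in minutes.
#' @export
plot_binary_trace <- function(decisions) {
  df <- tibble::tibble(time_s = decisions$times_s,
                       decision = decisions$binary)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60,
                                   y = .data$decision)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = c(0, 1), limits = c(-0.05, 1.05)) +
    ggplot2::labs(x = "time (min)", y = "seizure decision") +
    ggplot2::theme_minimal()
}

#' Plot the spatio-temporal colormap
#' @param grid A `colormap_grid` from [build_colormap()].
#' @return A ggplot tile plot, channels x time, 10 discrete colours.
#' @export
plot_colormap <- function(grid) {
  df <- tibble::tibble(
    channel = factor(rep(grid$channel_labels, times = length(grid$times_s)),
                     levels = rev(grid$channel_labels)),
    time_s = rep(grid$times_s, each = length(grid$channel_labels)),
    bin = factor(as.vector(grid$bins), levels = 0:9)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60, y = .data$channel,
                                   fill = .data$bin)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = stats::setNames(
      colormap_colours(), as.character(0:9)), drop = FALSE,
      name = "probability bin") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an aEEG trace on the semilog display scale
#' @param aeeg An `aeeg_trace` from [compute_aeeg()].
#' @return A ggplot envelope (ribbon) on the display scale, with the
#'   linear/log breakpoint at 10 marked.
#' @export
plot_aeeg <- function(aeeg) {
  ggplot2::ggplot(aeeg, ggplot2::aes(x = .data$time_s / 60)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower_disp,
                                      ymax = .data$upper_disp),
                         fill = "grey30", alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 10, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::scale_y_continuous(
      limits = c(0, 20),
      breaks = aeeg_semilog(c(0, 5, 10, 25, 50, 100)),
      labels = c(0, 5, 10, 25, 50, 100)) +
    ggplot2::labs(x = "time (min)", y = "amplitude (µV, semilog)") +
    ggplot2::theme_minimal()
}

#' Four-panel display bundle
#'
#' Assembles the bedside view: aEEG envelope, binary decisions,
#' threshold-coloured probability trace, and the spatio-temporal colormap.
#'
#' @param rec An [eeg_recording()] (for the aEEG panel).
#' @param trace A `probability_trace`.
#' @param decisions A `decision_trace` (defaults to `binarize(trace)`).
#' @param aeeg_channel Channel shown in the aEEG panel (default 1).
#' @return A `display_bundle` list of the four ggplot panels
#'   (`aeeg`, `binary`, `probability`, `colormap`).
#' @export
display_bundle <- function(rec, trace, decisions = binarize(trace),
                           aeeg_channel = 1) {
  structure(
    list(
      aeeg = plot_aeeg(compute_aeeg(rec, aeeg_channel)),
      binary = plot_binary_trace(decisions),
      probability = plot_probability_trace(trace, decisions$theta),
      colormap = plot_colormap(build_colormap(trace))
    ),
    class = "display_bundle"
  )
}
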