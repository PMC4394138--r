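#' Audification configuration
#'
#' Parameters of the EEG audification chain: phase-vocoder time stretch,
#' output sampling rate, STFT geometry, probability-controlled gain and
#' the hemisphere assignment of the bipolar channels. With the defaults
#' (stretch 100, output 32 kHz) the 32 Hz EEG band 0.5-13 Hz maps to
#' 0.5-13 kHz and one hour of EEG plays in roughly six minutes (real-time
#' divided by 10).
#'
#' @param stretch_factor Time-stretch ratio (default 100, `>= 1`).
#' @param output_rate_hz Output audio rate in Hz (default 32000).
#' @param window STFT window length in samples at 32 Hz (default 64, 2 s).
#' @param hop STFT hop in samples (default 16).
#' @param gain_floor Minimum gain in `[0, 1)` applied where the seizure
#'   probability is 0, keeping background EEG audible (default 0.2).
#' @param ref_amplitude_uv Amplitude mapped to full scale before gain
#'   (default 150 microvolts).
#' @param use_fused If `TRUE`, gain follows the fused probability; by
#'   default each rendered channel follows its own smoothed probability.
#' @param hemisphere_map Named character vector mapping channel labels to
#'   `"left"`/`"right"` (default [default_hemisphere_map()]).
#' @return An `audify_config` list.
#' @export
audify_config <- function(stretch_factor = 100, output_rate_hz = 32000,
                          window = 64, hop = 16, gain_floor = 0.2,
                          ref_amplitude_uv = 150, use_fused = FALSE,
                          hemisphere_map = default_hemisphere_map()) {
  stopifnot(stretch_factor >= 1, output_rate_hz > 0,
            window >= 4, hop >= 1, hop <= window,
            gain_floor >= 0, gain_floor < 1)
  structure(
    list(stretch_factor = stretch_factor, output_rate_hz = output_rate_hz,
         window = window, hop = hop, gain_floor = gain_floor,
         ref_amplitude_uv = ref_amplitude_uv, use_fused = use_fused,
         hemisphere_map = hemisphere_map),
    class = "audify_config"
  )
}

#' Default hemisphere assignment of the neonatal bipolar channels
#'
#' Channels containing the midline electrode Cz are assigned by their
#' lateral electrode (C4-Cz right, Cz-C3 left).
#'
#' @return Named character vector, values `"left"`/`"right"`.
#' @export
default_hemisphere_map <- function() {
  c("F4-C4" = "right", "C4-O2" = "right", "T4-C4" = "right",
    "C4-Cz" = "right",
    "F3-C3" = "left", "C3-O1" = "left", "Cz-C3" = "left",
    "C3-T3" = "left")
}

princarg <- function(x) (x + pi) %% (2 * pi) - pi

# STFT with reflect center-padding; returns magnitude and phase,
# bins 0..window/2 (rows) x frames (columns)
stft_analysis <- function(x, window, hop) {
  pad <- window %/% 2
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  starts <- seq(1, length(xp) - window + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, window - 1) / window))
  frames <- matrix(xp[outer(seq_len(window) - 1, starts, "+")],
                   nrow = window)
  spec <- stats::mvfft(frames * w)[1:(window %/% 2 + 1), , drop = FALSE]
  list(mag = Mod(spec), phase = Arg(spec), n_frames = length(starts))
}

#' Phase-vocoder time stretch
#'
#' Stretches a mono signal by `factor` while preserving its short-time
#' spectral content: the STFT time base is resampled by the stretch
#' factor, magnitudes are linearly interpolated between analysis frames,
#' and phases are propagated per bin by the measured instantaneous
#' frequency, then the frames are resynthesized by windowed overlap-add.
#'
#' @param x Numeric signal (any rate; samples are rate-agnostic).
#' @param factor Stretch ratio `>= 1` (`1` is the identity stretch).
#' @param window STFT window length (default 64 samples, i.e. 2 s at
#'   32 Hz).
#' @param hop STFT hop (default 16 samples).
#' @return Stretched signal of length `round(length(x) * factor)`.
#' @export
phase_vocoder_stretch <- function(x, factor, window = 64, hop = 16) {
  if (length(x) < window) {
    stop("input shorter than one STFT window (", window, " samples)",
         call. = FALSE)
  }
  stopifnot(factor >= 1)
  A <- stft_analysis(x, window, hop)
  nf <- A$n_frames
  nbins <- window %/% 2 + 1
  omega <- 2 * pi * hop * (seq_len(nbins) - 1) / window
  # per-bin phase advance between consecutive analysis frames
  dp <- princarg(A$phase[, -1, drop = FALSE] -
                   A$phase[, -nf, drop = FALSE] - omega) + omega

  out_len <- round(length(x) * factor)
  n_steps <- floor(out_len / hop) + 1L
  w <- 0.5 * (1 - cos(2 * pi * seq(0, window - 1) / window))
  pad <- window %/% 2
  total <- (n_steps - 1L) * hop + window
  y <- numeric(total)
  wsum <- numeric(total)

  chunk <- 50000L
  carry_phase <- A$phase[, 1]
  for (a in seq(1L, n_steps, by = chunk)) {
    b <- min(a + chunk - 1L, n_steps)
    len <- b - a + 1L
    t <- (seq(a, b) - 1) / factor            # analysis position, 0-based
    fl <- pmin(floor(t), nf - 2L)
    frac <- t - fl
    m1 <- A$mag[, fl + 1L, drop = FALSE]
    m2 <- A$mag[, fl + 2L, drop = FALSE]
    magc <- m1 + (m2 - m1) * rep(frac, each = nbins)
    # phase increment into step i comes from the frame pair at step i-1
    t_prev <- (seq(a, b) - 2) / factor
    fl_prev <- pmax(pmin(floor(t_prev), nf - 2L), 0L)
    inc <- dp[, fl_prev + 1L, drop = FALSE]
    if (a == 1L) inc[, 1] <- 0               # first frame keeps its phase
    cs <- if (len == 1L) inc else t(apply(inc, 1, cumsum))
    ph <- carry_phase + cs
    carry_phase <- ph[, len]
    spec <- magc * exp(1i * ph)
    full <- rbind(spec, Conj(spec[(nbins - 1):2, , drop = FALSE]))
    frames <- Re(stats::mvfft(full, inverse = TRUE)) / window * w
    # overlap-add: frames within one residue class are exactly adjacent
    # (hop * window/hop = window), so each class is one contiguous block
    n_res <- window %/% hop
    for (r in seq_len(n_res) - 1L) {
      if (r + 1L > len) next
      sel <- seq(r + 1L, len, by = n_res)
      gi <- (a - 1L) + sel                   # global step index
      start <- (gi[1] - 1L) * hop + 1L
      block <- as.vector(frames[, sel, drop = FALSE])
      rng <- start:(start + length(block) - 1L)
      y[rng] <- y[rng] + block
      wsum[rng] <- wsum[rng] + rep(w^2, length(sel))
    }
  }
  y <- y / pmax(wsum, 1e-8)
  y <- y[(pad + 1):length(y)]
  if (length(y) >= out_len) y[seq_len(out_len)] else c(y, numeric(out_len - length(y)))
}

#' Select one channel per hemisphere by cumulative seizure probability
#'
#' For each hemisphere, picks the channel whose smoothed probability trace
#' has the highest cumulative sum over the rendered segment; ties are
#' broken by channel order.
#'
#' @param trace A `probability_trace`.
#' @param hemisphere_map Named character vector, channel label to
#'   `"left"`/`"right"`.
#' @return Named list with `left` and `right` channel labels.
#' @export
select_hemisphere_channels <- function(trace,
                                       hemisphere_map = default_hemisphere_map()) {
  stopifnot(inherits(trace, "probability_trace"))
  pick <- function(side) {
    chans <- trace$channel_labels[
      hemisphere_map[trace$channel_labels] == side]
    chans <- chans[!is.na(chans)]
    if (length(chans) == 0) {
      stop("no channel assigned to the ", side, " hemisphere", call. = FALSE)
    }
    sums <- vapply(chans, function(ch) {
      sum(trace$per_channel[match(ch, trace$channel_labels), ])
    }, numeric(1))
    chans[which.max(sums)]
  }
  list(left = pick("left"), right = pick("right"))
}

#' Render stereo audified EEG
#'
#' The full audification chain: one channel per hemisphere is selected by
#' cumulative seizure probability, each selected channel is gain-modulated
#' by the (time-interpolated) probability trace — accentuating suspicious
#' segments while the gain floor keeps background audible — stretched by
#' the phase vocoder, and the pair is jointly normalized so no sample
#' exceeds full scale. Left/right audio channels correspond to the left/
#' right brain hemispheres.
#'
#' @param rec An [eeg_recording()] at 32 Hz (higher rates are resampled).
#' @param trace A `probability_trace`, or `NULL` for constant unit gain
#'   (hemisphere ties then fall to the first channel per side).
#' @param config An [audify_config()].
#' @return An `audio_rendering`: list with `samples` (n x 2 matrix,
#'   columns left/right, in `[-1, 1]`), `rate_hz`, `left_label`,
#'   `right_label`, `duration_s`.
#' @export
render_stereo <- function(rec, trace = NULL, config = audify_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$sample_rate_hz != 32) rec <- resample_to_32hz(rec)
  n <- ncol(rec$data)
  t_samp <- (seq_len(n) - 1) / 32

  if (is.null(trace)) {
    flat <- matrix(1, nrow = length(rec$channel_labels), ncol = 2,
                   dimnames = list(rec$channel_labels, NULL))
    trace <- probability_trace(flat, times_s = c(0, max(duration_s(rec), 4)),
                               smoothing_window = 1)
  }
  sel <- select_hemisphere_channels(trace, config$hemisphere_map)

  render_one <- function(label) {
    x <- channel_data(rec, label) / config$ref_amplitude_uv
    p <- if (config$use_fused) trace$fused else
      trace$per_channel[match(label, trace$channel_labels), ]
    p_s <- stats::approx(trace$times_s, p, xout = t_samp, rule = 2)$y
    gain <- config$gain_floor + (1 - config$gain_floor) * p_s
    phase_vocoder_stretch(x * gain, config$stretch_factor,
                          config$window, config$hop)
  }
  left <- render_one(sel$left)
  right <- render_one(sel$right)
  samples <- cbind(left = left, right = right)
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak
  structure(
    list(samples = samples, rate_hz = config$output_rate_hz,
         left_label = sel$left, right_label = sel$right,
         duration_s = nrow(samples) / config$output_rate_hz),
    class = "audio_rendering"
  )
}

#' @export
print.audio_rendering <- function(x, ...) {
  cat(sprintf(
    "<audio_rendering> %.1f s stereo @ %d Hz (L: %s, R: %s), peak %.3f\n",
    x$duration_s, x$rate_hz, x$left_label, x$right_label,
    max(abs(x$samples))))
  invisible(x)
}
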