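# shared fixture builders (all data generated in code)

# recording holding the given per-channel signals
make_recording <- function(signals, fs = 32, labels = NULL) {
  eeg_recording(do.call(rbind, signals), fs,
                labels %||% paste0("ch", seq_along(signals)))
}

# a feature_matrix built directly from a 3D array (epochs x channels x feats)
make_feature_matrix <- function(values, feature_names,
                                channel_labels = NULL, hop_s = 4) {
  structure(
    list(
      values = values,
      feature_names = feature_names,
      epoch_start_s = (seq_len(dim(values)[1]) - 1) * hop_s,
      hop_s = hop_s, length_s = 2 * hop_s,
      channel_labels = channel_labels %||% paste0("ch", seq_len(dim(values)[2]))
    ),
    class = "feature_matrix"
  )
}

# probability_trace from a plain channels x epochs matrix, 4 s hop,
# hop-aligned timestamps starting at 4 s
make_trace <- function(per_channel, labels = NULL) {
  per_channel <- as.matrix(per_channel)
  if (!is.null(labels)) rownames(per_channel) <- labels
  probability_trace(per_channel,
                    times_s = 4 * seq_len(ncol(per_channel)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# periodogram peak frequency of a signal (independent of package internals)
peak_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2)]
  (which.max(sp)) * fs / n
}

# band power via the periodogram (Parseval-scaled), [lo, hi] Hz
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi
  2 * sum(sp[sel])
}

# a small seizure-bearing simulation shared by several test files
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        duration_s = 200,
        seizure_events = seizure_events(60, 140, freq_hz = 2.5,
                                        amplitude_uv = 100,
                                        channels = list(1:2)),
        seed = 42
      )
      cache <<- simulate_recording(cfg)
    }
    cache
  }
})
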