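#' Simulation configuration for synthetic neonatal EEG
#'
#' Describes a synthetic multi-channel neonatal EEG record: a pink-noise
#' (1/f) background at a given RMS amplitude, plus rhythmic seizure
#' discharges on selected channels. Dominant neonatal seizure discharge
#' frequencies lie between 0.5 and 6 Hz, and events outside that band are
#' rejected.
#'
#' @param duration_s Record duration in seconds.
#' @param n_channels Number of channels (default 8, labelled with the
#'   standard neonatal bipolar pairs when 8).
#' @param sample_rate_hz Sampling rate in Hz (default 256).
#' @param seizure_events Data frame with columns `onset_s`, `offset_s`,
#'   `freq_hz` (discharge frequency, 0.5-6 Hz), `amplitude_uv` (peak
#'   amplitude of the fundamental) and a list-column `channels` of integer
#'   channel indices carrying the discharge. May be `NULL` for a
#'   seizure-free record.
#' @param background_amplitude_uv RMS amplitude of the 1/f background in
#'   microvolts (default 30, a typical moderately-abnormal neonatal
#'   background level).
#' @param seed Integer seed; fixing it makes the output byte-identical.
#'
#' @return A `simulation_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(
#'   duration_s = 120,
#'   seizure_events = seizure_events(30, 80, freq_hz = 2.5, channels = list(1:2))
#' )
simulation_config <- function(duration_s,
                              n_channels = 8,
                              sample_rate_hz = 256,
                              seizure_events = NULL,
                              background_amplitude_uv = 30,
                              seed = 1L) {
  stopifnot(duration_s > 0, n_channels >= 1, sample_rate_hz > 0)
  ev <- normalize_events(seizure_events, duration_s, n_channels)
  structure(
    list(
      duration_s = duration_s,
      n_channels = n_channels,
      sample_rate_hz = sample_rate_hz,
      seizure_events = ev,
      background_amplitude_uv = background_amplitude_uv,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Build a seizure-event table
#'
#' @param onset_s,offset_s Event boundaries in seconds.
#' @param freq_hz Discharge frequency per event, within 0.5-6 Hz.
#' @param amplitude_uv Peak amplitude of the discharge fundamental.
#' @param channels List of integer vectors: the channels each event affects.
#' @return A tibble suitable for `simulation_config(seizure_events = )`.
#' @export
seizure_events <- function(onset_s, offset_s, freq_hz = 2.5,
                           amplitude_uv = 100, channels = list(1L)) {
  n <- length(onset_s)
  tibble::tibble(
    onset_s = onset_s,
    offset_s = offset_s,
    freq_hz = rep_len(freq_hz, n),
    amplitude_uv = rep_len(amplitude_uv, n),
    channels = rep_len(channels, n)
  )
}

normalize_events <- function(ev, duration_s, n_channels) {
  if (is.null(ev) || NROW(ev) == 0) {
    return(tibble::tibble(
      onset_s = numeric(), offset_s = numeric(), freq_hz = numeric(),
      amplitude_uv = numeric(), channels = list()
    ))
  }
  ev <- tibble::as_tibble(ev)
  req <- c("onset_s", "offset_s", "freq_hz", "amplitude_uv", "channels")
  if (!all(req %in% names(ev))) {
    stop("seizure_events needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ev <- ev[order(ev$onset_s), ]
  if (any(ev$onset_s < 0) || any(ev$offset_s > duration_s)) {
    stop("seizure events must lie within [0, duration_s]", call. = FALSE)
  }
  if (any(ev$onset_s >= ev$offset_s)) {
    stop("seizure events must satisfy onset < offset", call. = FALSE)
  }
  if (nrow(ev) > 1 && any(ev$onset_s[-1] < ev$offset_s[-nrow(ev)])) {
    stop("seizure events must be non-overlapping", call. = FALSE)
  }
  if (any(ev$freq_hz < 0.5 | ev$freq_hz > 6)) {
    stop("discharge frequencies must lie in [0.5, 6] Hz", call. = FALSE)
  }
  bad <- vapply(ev$channels, function(ch) {
    any(ch < 1 | ch > n_channels)
  }, logical(1))
  if (any(bad)) stop("event channel indices out of range", call. = FALSE)
  ev
}

#' Standard neonatal bipolar channel labels
#'
#' The eight bipolar derivations used by the detector, covering both
#' hemispheres of the neonatal 10-20 placement.
#'
#' @return Character vector of 8 labels.
#' @export
neonatal_bipolar_labels <- function() {
  c("F4-C4", "C4-O2", "F3-C3", "C3-O1",
    "T4-C4", "C4-Cz", "Cz-C3", "C3-T3")
}

# white Gaussian noise shaped to a 1/f power spectrum, unit RMS
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- seq(0, n - 1) / n                       # normalized frequency grid
  f <- pmin(f, 1 - f)                          # two-sided -> |f|
  f[f < 1 / n] <- 1 / n                        # clamp DC
  w <- 1 / sqrt(f)                             # amplitude ~ f^-1/2 => power ~ 1/f
  x <- Re(stats::fft(spec * w, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

# rhythmic discharge: Hann-enveloped sinusoid + half-amplitude 2nd harmonic
discharge_waveform <- function(t_rel, dur, freq_hz, amplitude_uv, phase) {
  env <- 0.5 * (1 - cos(2 * pi * t_rel / dur))       # Hann over the event
  amplitude_uv * env *
    (sin(2 * pi * freq_hz * t_rel + phase) +
       0.5 * sin(4 * pi * freq_hz * t_rel + 2 * phase))
}

#' Simulate a synthetic neonatal EEG recording
#'
#' Generates a multi-channel record whose background is 1/f-shaped Gaussian
#' noise at the configured RMS amplitude; each seizure event adds an
#' amplitude-modulated rhythmic discharge (fundamental plus half-amplitude
#' second harmonic under a Hann envelope) to its listed channels. The
#' returned annotations equal the configured event intervals.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `recording` (an [eeg_recording()]),
#'   `annotations` (an [annotation_track()] of the configured events) and
#'   `channel_annotations` (a list, per channel, of the events affecting
#'   that channel — the per-channel ground truth).
#' @export
#' @examples
#' sim <- simulate_recording(simulation_config(duration_s = 30))
#' sim$recording
simulate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- round(config$duration_s * config$sample_rate_hz)
  fs <- config$sample_rate_hz
  labels <- if (config$n_channels == 8) {
    neonatal_bipolar_labels()
  } else {
    paste0("ch", seq_len(config$n_channels))
  }

  set.seed(config$seed)
  data <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    data[ch, ] <- config$background_amplitude_uv * pink_noise(n)
  }

  ev <- config$seizure_events
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      idx0 <- floor(ev$onset_s[i] * fs)
      idx1 <- min(ceiling(ev$offset_s[i] * fs), n)
      idx <- seq(idx0 + 1, idx1)
      t_rel <- (idx - 1) / fs - ev$onset_s[i]
      dur <- ev$offset_s[i] - ev$onset_s[i]
      for (ch in ev$channels[[i]]) {
        phase <- stats::runif(1, 0, 2 * pi)
        data[ch, idx] <- data[ch, idx] +
          discharge_waveform(t_rel, dur, ev$freq_hz[i], ev$amplitude_uv[i],
                             phase)
      }
    }
  }

  ann <- annotation_track(ev$onset_s, ev$offset_s)
  ch_ann <- lapply(seq_len(config$n_channels), function(ch) {
    if (nrow(ev) == 0) return(annotation_track())
    hit <- vapply(ev$channels, function(cc) ch %in% cc, logical(1))
    annotation_track(ev$onset_s[hit], ev$offset_s[hit])
  })
  names(ch_ann) <- labels

  list(
    recording = eeg_recording(data, fs, labels),
    annotations = ann,
    channel_annotations = ch_ann
  )
}

#' Simulate a cohort of synthetic records
#'
#' Draws a set of independent records sharing the generator defaults:
#' per record, `events_per_record` seizures with onsets spread over the
#' record, durations uniform in `event_duration_s`, discharge frequencies
#' uniform in 0.5-6 Hz, fixed discharge amplitude, and a random contiguous
#' run of 2-4 affected channels per event (focal-to-regional spread).
#'
#' @param n_records Number of records (patients).
#' @param duration_s Duration of each record in seconds (default 900).
#' @param events_per_record Seizures per record (default 2).
#' @param event_duration_s Length-2 range of event durations in seconds.
#' @param amplitude_uv Discharge amplitude in microvolts (default 100).
#' @param background_amplitude_uv Background RMS (default 30).
#' @param sample_rate_hz Sampling rate (default 256).
#' @param seed Integer seed for the whole cohort.
#' @return A list of `simulate_recording()` results, one per record.
#' @export
simulate_cohort <- function(n_records = 6, duration_s = 900,
                            events_per_record = 2,
                            event_duration_s = c(60, 120),
                            amplitude_uv = 100,
                            background_amplitude_uv = 30,
                            sample_rate_hz = 256,
                            seed = 1L) {
  set.seed(seed)
  record_seeds <- sample.int(.Machine$integer.max, n_records)
  lapply(seq_len(n_records), function(r) {
    # carve the record into equal slots so events never overlap
    slot <- duration_s / events_per_record
    durs <- stats::runif(events_per_record, event_duration_s[1],
                         min(event_duration_s[2], slot - 20))
    onsets <- (seq_len(events_per_record) - 1) * slot +
      stats::runif(events_per_record, 10, pmax(10.5, slot - durs - 10))
    first <- sample.int(6, events_per_record, replace = TRUE)
    width <- sample(2:4, events_per_record, replace = TRUE)
    chans <- lapply(seq_len(events_per_record), function(i) {
      seq(first[i], min(first[i] + width[i] - 1, 8))
    })
    ev <- seizure_events(
      onset_s = onsets, offset_s = onsets + durs,
      freq_hz = stats::runif(events_per_record, 0.5, 6),
      amplitude_uv = amplitude_uv, channels = chans
    )
    simulate_recording(simulation_config(
      duration_s = duration_s, sample_rate_hz = sample_rate_hz,
      seizure_events = ev,
      background_amplitude_uv = background_amplitude_uv,
      seed = record_seeds[r]
    ))
  })
}
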