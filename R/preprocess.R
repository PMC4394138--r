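#' Bipolar montage specification
#'
#' An ordered set of (anode, cathode) electrode label pairs. The default is
#' the eight neonatal derivations used throughout the detector:
#' F4-C4, C4-O2, F3-C3, C3-O1, T4-C4, C4-Cz, Cz-C3, C3-T3.
#'
#' @param anode,cathode Character vectors of electrode labels.
#' @return A tibble of class `montage_spec` with columns `anode`, `cathode`.
#' @export
montage_spec <- function(anode, cathode) {
  stopifnot(length(anode) == length(cathode), length(anode) >= 1)
  out <- tibble::tibble(anode = as.character(anode),
                        cathode = as.character(cathode))
  class(out) <- c("montage_spec", class(out))
  out
}

#' @rdname montage_spec
#' @export
default_montage <- function() {
  montage_spec(
    anode   = c("F4", "C4", "F3", "C3", "T4", "C4", "Cz", "C3"),
    cathode = c("C4", "O2", "C3", "O1", "C4", "Cz", "C3", "T3")
  )
}

#' Derive bipolar channels from a referential recording
#'
#' Each output channel is the samplewise difference anode - cathode,
#' labelled `"anode-cathode"`.
#'
#' @param rec An [eeg_recording()] containing every montage electrode.
#' @param montage A [montage_spec()]; defaults to the neonatal 8-pair set.
#' @return An [eeg_recording()] with one channel per pair.
#' @export
derive_bipolar <- function(rec, montage = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  needed <- unique(c(montage$anode, montage$cathode))
  missing <- setdiff(needed, rec$channel_labels)
  if (length(missing) > 0) {
    stop("montage electrode(s) missing from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- t(vapply(seq_len(nrow(montage)), function(i) {
    rec$data[montage$anode[i], ] - rec$data[montage$cathode[i], ]
  }, numeric(ncol(rec$data))))
  labels <- paste0(montage$anode, "-", montage$cathode)
  eeg_recording(data, rec$sample_rate_hz, labels, rec$start_time_s)
}

# zero-phase application of a symmetric odd-length FIR filter: plain linear
# convolution (zero-padded edges) with the group delay trimmed from both ends
fir_zero_phase <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  half <- (length(h) - 1) / 2
  y <- stats::convolve(x, rev(h), type = "open")
  y[(half + 1):(length(y) - half)]
}

# anti-aliasing low-pass: linear-phase FIR, ~1 s long, Hamming-windowed
antialias_filter <- function(fs, cutoff_hz = 12.8) {
  ord <- 2L * floor(fs / 2)           # even order -> odd length, integer delay
  ord <- max(ord, 32L)
  signal::fir1(ord, cutoff_hz / (fs / 2), type = "low")
}

#' Resample a recording to 32 Hz with 12.8 Hz anti-aliasing
#'
#' Applies a zero-phase low-pass FIR filter with cutoff 12.8 Hz, then maps
#' the filtered signal onto the exact 32 Hz sample grid (index decimation
#' when the source rate is an integer multiple of 32 Hz; cubic-spline
#' interpolation otherwise). Zero-phase filtering means annotation times
#' need no group-delay correction.
#'
#' @param rec An [eeg_recording()] with `sample_rate_hz >= 32`.
#' @param target_hz Target rate (fixed at 32 Hz by the pipeline; exposed
#'   for testing).
#' @param cutoff_hz Anti-alias cutoff (default 12.8 Hz).
#' @return An [eeg_recording()] at `target_hz`.
#' @export
resample_to_32hz <- function(rec, target_hz = 32, cutoff_hz = 12.8) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  if (fs < target_hz) {
    stop("sampling rate below ", target_hz, " Hz cannot be resampled up",
         call. = FALSE)
  }
  if (fs == target_hz) return(rec)
  h <- antialias_filter(fs, cutoff_hz)
  n_out <- floor(ncol(rec$data) * target_hz / fs)
  ratio <- fs / target_hz
  integer_ratio <- abs(ratio - round(ratio)) < 1e-9
  data <- matrix(0, nrow = nrow(rec$data), ncol = n_out)
  t_out <- (seq_len(n_out) - 1) / target_hz
  for (ch in seq_len(nrow(rec$data))) {
    y <- fir_zero_phase(rec$data[ch, ], h)
    if (integer_ratio) {
      data[ch, ] <- y[1 + (seq_len(n_out) - 1) * round(ratio)]
    } else {
      t_in <- (seq_along(y) - 1) / fs
      data[ch, ] <- stats::spline(t_in, y, xout = t_out, method = "fmm")$y
    }
  }
  eeg_recording(data, target_hz, rec$channel_labels, rec$start_time_s)
}

#' Split a 32 Hz recording into 8 s epochs with 50% overlap
#'
#' Epochs start at 0, 4, 8, ... seconds (4 s hop); trailing samples that do
#' not fill a whole epoch are dropped. A recording shorter than one epoch
#' yields zero epochs.
#'
#' @param rec An [eeg_recording()] at 32 Hz.
#' @param length_s Epoch length in seconds (default 8).
#' @param overlap Fractional overlap between consecutive epochs (default 0.5).
#' @return An `epoch_tensor`: list with `values` (epochs x channels x
#'   samples array), `epoch_start_s`, `sample_rate_hz`, `channel_labels`.
#' @export
make_epochs <- function(rec, length_s = 8, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  win <- round(length_s * fs)
  hop <- round(win * (1 - overlap))
  n <- ncol(rec$data)
  n_ep <- if (n < win) 0L else (n - win) %/% hop + 1L
  vals <- array(0, dim = c(n_ep, nrow(rec$data), win))
  starts <- numeric(n_ep)
  for (k in seq_len(n_ep)) {
    idx <- ((k - 1) * hop + 1):((k - 1) * hop + win)
    vals[k, , ] <- rec$data[, idx, drop = FALSE]
    starts[k] <- (idx[1] - 1) / fs
  }
  structure(
    list(
      values = vals,
      epoch_start_s = starts,
      sample_rate_hz = fs,
      length_s = length_s,
      hop_s = hop / fs,
      channel_labels = rec$channel_labels
    ),
    class = "epoch_tensor"
  )
}

#' @export
print.epoch_tensor <- function(x, ...) {
  cat(sprintf("<epoch_tensor> %d epochs x %d channels x %d samples (%g s hop)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$hop_s))
  invisible(x)
}

#' Run the full front end: montage, resampling, epoching
#'
#' @param rec An [eeg_recording()], referential or already bipolar.
#' @param montage A [montage_spec()], or `NULL` if `rec` is already in the
#'   desired montage.
#' @return An `epoch_tensor` at 32 Hz.
#' @export
preprocess_recording <- function(rec, montage = NULL) {
  if (!is.null(montage)) rec <- derive_bipolar(rec, montage)
  make_epochs(resample_to_32hz(rec))
}
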