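#' Multi-channel EEG recording
#'
#' Container for a block of continuous multi-channel EEG: a channels x
#' samples matrix of voltages in microvolts together with its sampling rate
#' and channel labels. Every stage of the detection pipeline consumes and
#' produces this object.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel labels, one per
#'   row of `data`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param start_time_s Time of the first sample in seconds (default 0).
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(64), 2, 32), 32, c("F4", "C4"))
#' n_samples(rec)
eeg_recording <- function(data, sample_rate_hz, channel_labels = NULL,
                          start_time_s = 0) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must have one entry per channel", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(
      data = data,
      sample_rate_hz = sample_rate_hz,
      channel_labels = channel_labels,
      start_time_s = start_time_s
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$sample_rate_hz, duration_s(x)
  ))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec An `eeg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$sample_rate_hz

#' Extract one channel as a numeric vector
#' @param rec An `eeg_recording`.
#' @param channel Channel label or index.
#' @return Numeric vector of samples in microvolts.
#' @export
channel_data <- function(rec, channel) {
  if (is.character(channel)) {
    if (!channel %in% rec$channel_labels) {
      stop("unknown channel: ", channel, call. = FALSE)
    }
    rec$data[channel, ]
  } else {
    rec$data[channel, ]
  }
}

#' Seizure annotation track
#'
#' An ordered set of half-open seizure intervals `[onset_s, offset_s)` in
#' seconds. Ground-truth annotations and detector output share this shape.
#'
#' @param onset_s Numeric vector of onsets in seconds (or a two-column
#'   data frame / matrix of onsets and offsets, in which case `offset_s`
#'   is ignored).
#' @param offset_s Numeric vector of offsets in seconds.
#'
#' @return A tibble of class `annotation_track` with columns `onset_s` and
#'   `offset_s`, sorted by onset.
#' @export
#' @examples
#' annotation_track(c(10, 100), c(40, 160))
annotation_track <- function(onset_s = numeric(), offset_s = numeric()) {
  if (is.data.frame(onset_s) || is.matrix(onset_s)) {
    tab <- as.data.frame(onset_s)
    offset_s <- tab[[2]]
    onset_s <- tab[[1]]
  }
  stopifnot(length(onset_s) == length(offset_s))
  ord <- order(onset_s, offset_s)
  onset_s <- as.numeric(onset_s)[ord]
  offset_s <- as.numeric(offset_s)[ord]
  if (any(onset_s >= offset_s)) {
    stop("every annotation must satisfy onset < offset", call. = FALSE)
  }
  if (length(onset_s) > 1 && any(onset_s[-1] < offset_s[-length(offset_s)])) {
    stop("annotations must be non-overlapping", call. = FALSE)
  }
  out <- tibble::tibble(onset_s = onset_s, offset_s = offset_s)
  class(out) <- c("annotation_track", class(out))
  out
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %d event(s)\n", nrow(x)))
  NextMethod()
}

# total annotated seconds
annotation_duration <- function(ann) sum(ann$offset_s - ann$onset_s)

# TRUE for each query interval [a, b) that overlaps any annotation
overlaps_any <- function(a, b, ann) {
  if (nrow(ann) == 0) return(rep(FALSE, length(a)))
  vapply(seq_along(a), function(i) {
    any(a[i] < ann$offset_s & b[i] > ann$onset_s)
  }, logical(1))
}

# merge possibly-overlapping intervals (rows onset/offset) into a valid track
merge_intervals <- function(onset, offset) {
  if (length(onset) == 0) return(annotation_track())
  ord <- order(onset)
  onset <- onset[ord]; offset <- offset[ord]
  mo <- onset[1]; mf <- offset[1]
  keep_on <- numeric(); keep_off <- numeric()
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= mf) {
      mf <- max(mf, offset[i])
    } else {
      keep_on <- c(keep_on, mo); keep_off <- c(keep_off, mf)
      mo <- onset[i]; mf <- offset[i]
    }
  }
  annotation_track(c(keep_on, mo), c(keep_off, mf))
}

#' Read / write annotation CSV files
#'
#' Annotations are exchanged as plain CSV with columns `onset_s,offset_s`,
#' one seizure event per row.
#'
#' @param ann An `annotation_track`.
#' @param path File path.
#' @return `read_annotations()` returns an `annotation_track`;
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[c("onset_s", "offset_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path)
  annotation_track(tab$onset_s, tab$offset_s)
}
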