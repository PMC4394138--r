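#' Write an EEG recording to an EDF file
#'
#' Minimal European Data Format writer for continuous recordings: one data
#' record per second, all channels at the same integer sampling rate,
#' 16-bit samples mapped linearly from the physical range (default
#' +/- 500 microvolts) onto the full digital range. Samples outside the
#' physical range are clipped. Trailing samples that do not fill a whole
#' 1 s data record are dropped.
#'
#' @param rec An [eeg_recording()] with an integer sampling rate.
#' @param path Output file path.
#' @param physical_range Length-2 physical range in microvolts.
#' @return `path`, invisibly.
#' @export
#' @seealso [read_edf()]
write_edf <- function(rec, path, physical_range = c(-500, 500)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  if (fs != round(fs)) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(fs)
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record", call. = FALSE)

  pmin_ <- physical_range[1]; pmax_ <- physical_range[2]
  dmin <- -32768L; dmax <- 32767L

  pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),                               # version
    pad("X X X X", 80),                        # patient id (anonymous)
    pad("Startdate X X X X", 80),              # recording id
    pad("01.01.00", 8), pad("00.00.00", 8),    # date, time
    pad(256 + ns * 256, 8),                    # header bytes
    pad("", 44),                               # reserved
    pad(n_rec, 8),
    pad("1", 8),                               # record duration (s)
    pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(rep(pmin_, ns), 8)
  field(rep(pmax_, ns), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)                       # reserved

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((pmin(pmax(rec$data, pmin_), pmax_) - pmin_) * scale) + dmin
  dig <- matrix(as.integer(dig), nrow = ns)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.vector(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Counterpart of [write_edf()]: reads continuous EDF files in which all
#' signals share one sampling rate. Digital values are mapped back to the
#' physical (microvolt) scale.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdn <- function(width) {
    vapply(seq_len(ns), function(i) rd(width), "")
  }
  labels <- rdn(16)
  rdn(80); rdn(8)
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (length(unique(spr)) != 1) {
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  total <- n_rec * spr[1]
  data <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block)
  }
  for (s in seq_len(ns)) {
    data[s, ] <- (data[s, ] - dmin[s]) *
      (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s]) + pmin_[s]
  }
  eeg_recording(data, fs, labels)
}
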