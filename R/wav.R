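#' Write an audio rendering to a 16-bit PCM WAV file
#'
#' Plain RIFF/WAVE writer: 16-bit little-endian PCM, interleaved channels.
#' Samples are expected in `[-1, 1]` and are clipped to that range.
#'
#' @param audio An `audio_rendering` from [render_stereo()], or a numeric
#'   matrix (samples x channels) in `[-1, 1]`.
#' @param path Output path.
#' @param rate_hz Sampling rate; taken from the rendering when omitted.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, rate_hz = NULL) {
  if (inherits(audio, "audio_rendering")) {
    rate_hz <- rate_hz %||% audio$rate_hz
    samples <- audio$samples
  } else {
    samples <- as.matrix(audio)
    if (is.null(rate_hz)) stop("rate_hz required for a bare matrix",
                               call. = FALSE)
  }
  n_ch <- ncol(samples)
  n <- nrow(samples)
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  inter <- as.vector(t(matrix(pcm, nrow = n, ncol = n_ch)))
  data_bytes <- 2L * length(inter)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz * n_ch * 2), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return List with `samples` (samples x channels matrix in `[-1, 1]`)
#'   and `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  stopifnot(readChar(con, 4) == "RIFF")
  readBin(con, "integer", size = 4, endian = "little")
  stopifnot(readChar(con, 4) == "WAVE")
  rate <- NULL; n_ch <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      readBin(con, "integer", size = 2, endian = "little")
      n_ch <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "raw", n = sz - 8)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      samples <- t(matrix(pcm, nrow = n_ch)) / 32767
      return(list(samples = samples, rate_hz = rate))
    } else {
      readBin(con, "raw", n = sz)
    }
  }
}
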