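# Minimal RIFF/WAVE PCM audio I/O (16-bit integer and 32-bit float), enough
# to feed stimulus clips to the chromagram extractor.

#' Read a WAV file
#'
#' Supports PCM 16-bit and IEEE-float 32-bit, mono or multi-channel.
#'
#' @param path WAV path.
#' @return list with `samples` (numeric vector for mono, samples x channels
#'   matrix otherwise; in [-1, 1]) and `sr` (sample rate, Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, endian = "little", signed = signed)
  tag <- function() rawToChar(readBin(con, "raw", 4L))
  if (tag() != "RIFF") stop("not a RIFF file")
  ri(1L, 4L)
  if (tag() != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- tag()
    if (length(id) == 0L || nchar(id) < 4L) stop("malformed WAV: no data chunk")
    size <- ri(1L, 4L)
    if (id == "fmt ") {
      fmt <- list(audio_format = ri(1L, 2L), channels = ri(1L, 2L),
                  sr = ri(1L, 4L))
      ri(1L, 4L); ri(1L, 2L)                 # byte rate, block align
      fmt$bits <- ri(1L, 2L)
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        x <- ri(size / 2L, 2L) / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "double", n = size / 4L, size = 4L, endian = "little")
      } else stop("unsupported WAV encoding")
      if (fmt$channels > 1L)
        x <- matrix(x, ncol = fmt$channels, byrow = TRUE)
      return(list(samples = x, sr = fmt$sr))
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
}

#' Write a WAV file (PCM 16-bit)
#'
#' @param samples numeric vector (mono) or samples x channels matrix, values
#'   in [-1, 1] (clipped).
#' @param path output path.
#' @param sr sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sr = 44100L) {
  if (is.matrix(samples)) {
    channels <- ncol(samples)
    x <- as.vector(t(samples))
  } else {
    channels <- 1L
    x <- samples
  }
  pcm <- as.integer(pmin(pmax(round(x * 32767), -32768), 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL); wi(36L + n_bytes, 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wi(16L, 4L)
  wi(1L, 2L); wi(channels, 2L); wi(sr, 4L)
  wi(sr * channels * 2L, 4L); wi(channels * 2L, 2L); wi(16L, 2L)
  writeChar("data", con, eos = NULL); wi(n_bytes, 4L)
  wi(pcm, 2L)
  invisible(path)
}
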