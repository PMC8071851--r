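#' Construct an audio buffer
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel;
#'   amplitudes nominally in `[-1, 1]`.
#' @param sample_rate Sample rate in Hz.
#' @return A list of class `audio_buffer` with fields `samples` (matrix),
#'   `sample_rate`, `channels`.
#' @export
audio_buffer <- function(samples, sample_rate = 44100) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  dimnames(samples) <- NULL
  structure(
    list(samples = samples, sample_rate = sample_rate,
         channels = ncol(samples)),
    class = "audio_buffer"
  )
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer> %d ch, %d samples @ %d Hz (%.2f s), peak %.3f\n",
              x$channels, nrow(x$samples), x$sample_rate,
              nrow(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

# Peak-normalise so |sample| <= limit; leaves already-safe audio untouched
# and leaves digital silence silent.
normalize_peak <- function(buf, limit = 0.99) {
  peak <- max(abs(buf$samples))
  if (peak > limit) buf$samples <- buf$samples * (limit / peak)
  buf
}

#' Write an audio buffer as a PCM WAV file
#'
#' Plain RIFF/WAVE writer (16- or 24-bit integer PCM, little-endian). Output
#' is byte-identical for identical inputs.
#'
#' @param buf An [audio_buffer()].
#' @param path Output file path.
#' @param bits 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(buf, path, bits = 16) {
  stopifnot(inherits(buf, "audio_buffer"), bits %in% c(16, 24))
  x <- t(buf$samples)           # interleave channels
  x <- pmax(pmin(as.numeric(x), 1), -1)
  scale <- 2^(bits - 1) - 1
  ints <- as.integer(round(x * scale))
  n_bytes <- length(ints) * bits / 8
  block_align <- buf$channels * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(buf$channels), con, size = 2, endian = "little")
  writeBin(as.integer(buf$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(buf$sample_rate * block_align), con, size = 4,
           endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(ints, con, size = 2, endian = "little")
  } else {
    b <- ints %% (2^24)
    raw3 <- rbind(b %% 256, (b %/% 256) %% 256, (b %/% 65536) %% 256)
    writeBin(as.raw(raw3), con)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Counterpart of [write_wav()]; supports 16- and 24-bit integer PCM.
#'
#' @param path WAV file path.
#' @return An [audio_buffer()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") {
    abort("not a RIFF/WAVE file", class = "breathsync_io_error")
  }
  channels <- 1L; rate <- 44100L; bits <- 16L
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found",
                                                class = "breathsync_io_error")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      n <- size / (bits / 8)
      if (bits == 16) {
        ints <- readBin(con, integer(), n = n, size = 2, endian = "little")
      } else {
        raw3 <- matrix(as.integer(readBin(con, raw(), n = size)), nrow = 3)
        ints <- raw3[1, ] + 256 * raw3[2, ] + 65536 * raw3[3, ]
        ints <- ifelse(ints >= 2^23, ints - 2^24, ints)
      }
      x <- ints / (2^(bits - 1) - 1)
      return(audio_buffer(matrix(x, ncol = channels, byrow = TRUE), rate))
    } else {
      readBin(con, raw(), n = size)
    }
  }
}
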