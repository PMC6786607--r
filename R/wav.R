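# Minimal RIFF/WAVE PCM reading and writing (16-bit integer samples).

#' Write a stereo waveform to a 16-bit PCM WAV file
#'
#' Samples are interpreted on the digital full scale (\eqn{|x| \le 1}) and
#' quantized to 16-bit integers; values outside \eqn{[-1, 1]} are clipped
#' with a warning.
#'
#' @param left,right Numeric sample vectors of equal length.
#' @param path Output file path.
#' @param sample_rate Sampling rate, Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(left, right, path, sample_rate = 44100) {
  stopifnot(length(left) == length(right))
  x <- rbind(left, right)
  if (any(abs(x) > 1)) {
    warning("samples outside [-1, 1] clipped on WAV export")
    x <- pmin(pmax(x, -1), 1)
  }
  pcm <- as.integer(round(x * 32767))
  n_channels <- 2L
  bytes_per_sample <- 2L
  data_size <- length(pcm) * bytes_per_sample
  byte_rate <- sample_rate * n_channels * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_channels, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(n_channels * bytes_per_sample, con, size = 2, endian = "little")
  writeBin(8L * bytes_per_sample, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]; supports uncompressed mono or stereo
#' 16-bit PCM only.
#'
#' @param path WAV file path.
#' @return List with `left`, `right` (equal to `left` for mono) and
#'   `sample_rate`; samples on the \eqn{[-1, 1]} full scale.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  sample_rate <- NULL
  n_channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only uncompressed PCM is supported")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      rest <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (rest[2] != 16) stop("only 16-bit PCM is supported")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", n = size / 2, size = 2,
                     signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  x <- pcm / 32767
  if (n_channels == 2) {
    list(left = x[c(TRUE, FALSE)], right = x[c(FALSE, TRUE)],
         sample_rate = sample_rate)
  } else {
    list(left = x, right = x, sample_rate = sample_rate)
  }
}
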