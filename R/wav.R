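#' Read and write mono PCM WAV files
#'
#' Minimal RIFF/WAVE I/O for the audio this package produces and consumes:
#' single-channel integer PCM at 8, 16, 24 or 32 bits. `write_wav()` always
#' writes 16-bit PCM; samples are expected in [-1, 1] and are clipped
#' otherwise.
#'
#' @param path File path.
#' @param samples Numeric vector of samples in [-1, 1].
#' @param sample_rate Sample rate in Hz.
#' @return `read_wav()` returns a list with `samples` (numeric in [-1, 1])
#'   and `sample_rate`; `write_wav()` returns `path` invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) >= 1, sample_rate > 0)
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(pmin(32767, round(x * 32768)))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort(sprintf("'%s' is not a RIFF file", path))
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) abort(sprintf("'%s' is not a WAVE file", path))
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) abort("only integer PCM WAV is supported")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", n = extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) abort("malformed WAV: data chunk before fmt chunk")
      if (channels != 1L) abort("only mono WAV is supported")
      if (bits == 8L) {
        raw8 <- readBin(con, "integer", n = size, size = 1, signed = FALSE)
        samples <- (raw8 - 128) / 128
      } else if (bits == 16L) {
        samples <- readBin(con, "integer", n = size %/% 2L, size = 2,
                           endian = "little") / 32768
      } else if (bits == 24L) {
        b <- as.integer(readBin(con, "raw", n = size))
        m <- matrix(b[seq_len(3L * (size %/% 3L))], nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else if (bits == 32L) {
        samples <- readBin(con, "integer", n = size %/% 4L, size = 4,
                           endian = "little") / 2147483648
      } else {
        abort(sprintf("unsupported bit depth: %d", bits))
      }
      break
    } else {
      invisible(readBin(con, "raw", n = size + (size %% 2L)))
    }
  }
  if (is.null(samples)) abort(sprintf("no data chunk found in '%s'", path))
  list(samples = samples, sample_rate = sample_rate)
}
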