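#' Minimal WAV input/output
#'
#' Reads and writes RIFF/WAVE files: PCM 16- or 24-bit and IEEE float32,
#' mono or stereo. Samples are exchanged as normalized full-scale doubles in
#' \[-1, 1\], one column per channel.
#'
#' @param path file path.
#' @return `read_wav`: list with `samples` (numeric matrix, one column per
#'   channel) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file", call. = FALSE)
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        bits = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"))
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV", call. = FALSE)
  n_bytes <- fmt$bits %/% 8
  n_samp <- length(data_raw) %/% (n_bytes * fmt$channels)
  if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "double", n_samp * fmt$channels, size = 4,
                 endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", n_samp * fmt$channels, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    b <- as.integer(data_raw)
    i1 <- seq(1, length(b), by = 3)
    v <- b[i1] + 256 * b[i1 + 1] + 65536 * b[i1 + 2]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits, " bit)", call. = FALSE)
  }
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE),
       sample_rate = fmt$sample_rate)
}

#' @rdname read_wav
#' @param samples numeric vector (mono) or matrix with one column per channel,
#'   full-scale \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param bits 16, 24 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  channels <- ncol(samples)
  x <- as.numeric(t(samples))  # interleave
  n_bytes <- bits %/% 8
  data_len <- length(x) * n_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt_code <- if (bits == 32) 3L else 1L
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * channels * n_bytes), con, size = 4,
           endian = "little")
  writeBin(as.integer(channels * n_bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(x, con, size = 4, endian = "little")
  } else if (bits == 16) {
    v <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else if (bits == 24) {
    v <- round(pmax(-1, pmin(1, x)) * (2^23 - 1))
    v <- ifelse(v < 0, v + 2^24, v)
    b <- as.raw(c(rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)))
    writeBin(b, con)
  } else {
    stop("unsupported bit depth", call. = FALSE)
  }
  invisible(path)
}
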