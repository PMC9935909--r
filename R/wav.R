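#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed audio. Supports 8/16/24/32-bit
#' integer PCM (format code 1) and 32/64-bit IEEE float (format code 3).
#' Multi-channel files are reduced to the first channel. Integer samples are
#' scaled to \[-1, 1\] by the two's-complement full scale (16-bit: x / 32768,
#' so -32768 maps to -1.0 and +32767 to +0.999969...).
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal()] with `fs` taken from the file header.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE payload: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1, size = 2, signed = FALSE, endian = "little"),
        channels  = readBin(body[3:4], "integer", 1, size = 2, signed = FALSE, endian = "little"),
        fs        = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits      = readBin(body[15:16], "integer", 1, size = 2, signed = FALSE, endian = "little")
      )
      if (fmt$format == 0xFFFE && sz >= 40) {  # WAVE_FORMAT_EXTENSIBLE: subformat GUID
        fmt$format <- readBin(body[25:26], "integer", 1, size = 2, signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path, call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0L) {
    stop("WAV file has no audio data: ", path, call. = FALSE)
  }

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$format),
    "1" = {
      if (fmt$bits == 8L) {
        (readBin(data_raw, "integer", n_total, size = 1, signed = FALSE) - 128) / 128
      } else if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n_total, size = 2, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        b <- as.integer(data_raw)
        i1 <- b[seq(1L, 3L * n_total, by = 3L)]
        i2 <- b[seq(2L, 3L * n_total, by = 3L)]
        i3 <- b[seq(3L, 3L * n_total, by = 3L)]
        v <- i1 + 256 * i2 + 65536 * i3
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$bits == 32L) {
        readBin(data_raw, "integer", n_total, size = 4, endian = "little") / 2147483648
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
      }
    },
    "3" = readBin(data_raw, "numeric", n_total, size = bytes, endian = "little"),
    stop("unsupported WAV format code: ", fmt$format, call. = FALSE)
  )

  if (fmt$channels > 1L) {
    x <- x[seq(1L, length(x), by = fmt$channels)]
  }
  if (length(x) == 0L) stop("WAV file contains zero samples: ", path, call. = FALSE)
  audio_signal(x, fmt$fs)
}

#' Write an audio signal as a 16-bit PCM WAV file
#'
#' Samples are clamped to \[-1, 1\] and quantized as `round(x * 32768)`
#' clipped to the signed 16-bit range, matching the [read_wav()] scaling so a
#' write/read round trip preserves samples to 16-bit quantization.
#'
#' @param signal An [audio_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  signal <- as_audio_signal(signal)
  x <- pmin(1, pmax(-1, signal$samples))
  q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n <- length(q)
  fs <- as.integer(round(signal$fs))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
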