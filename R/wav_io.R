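#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings produced by common
#' recording software: integer PCM (8/16/24/32 bit) and IEEE float32/64,
#' mono or multi-channel. Samples are returned as doubles scaled to
#' approximately \code{[-1, 1]}.
#'
#' @param path Path to a \code{.wav} file.
#' @return A list with elements \code{samples} (numeric matrix, one column
#'   per channel), \code{rate} (sampling rate in Hz), \code{bits} and
#'   \code{channels}.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      # WAVE_FORMAT_EXTENSIBLE carries the real format code in the extension
      if (fmt$format == 65534L && size >= 40) {
        fmt$format <- readBin(fmt_raw[25:26], "integer", 1, 2, signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)  # chunks are word-aligned
      next
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("missing fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0) stop("zero-length audio: ", path)

  bytes <- fmt$bits %/% 8L
  n_tot <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$format),
    "1" = {  # integer PCM
      if (fmt$bits == 8L) {
        as.numeric(readBin(data_raw, "integer", n_tot, 1, signed = FALSE)) / 128 - 1
      } else if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n_tot, 2, signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        m <- matrix(as.integer(data_raw), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$bits == 32L) {
        readBin(data_raw, "integer", n_tot, 4, endian = "little") / 2147483648
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data_raw, "double", n_tot, bytes, endian = "little"),
    stop("unsupported WAV format code: ", fmt$format)
  )
  if (n_tot %% fmt$channels != 0)
    x <- x[seq_len(n_tot - n_tot %% fmt$channels)]
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE),
       rate = fmt$rate, bits = fmt$bits, channels = fmt$channels)
}

#' Write a WAV file
#'
#' Writes mono or multi-channel audio as 16-bit integer PCM. Values are
#' clipped to \code{[-1, 1]} before quantisation.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.numeric(samples), nrow(samples) > 0, rate > 0)
  x <- pmax(pmin(t(samples), 1), -1)          # interleave channels
  q <- as.integer(round(as.vector(x) * 32767))
  n_bytes <- length(q) * 2L
  ch <- ncol(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(as.integer(ch), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
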