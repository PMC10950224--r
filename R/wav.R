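# Minimal PCM WAV I/O (16/24-bit, mono or first channel), canonical RIFF
# layout. Amplitudes are mapped to [-1, 1].

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in \[-1, 1\] (values are clamped).
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(length(samples) > 0, rate > 0)
  pcm <- as.integer(round(clamp(samples, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Supports 16- and 24-bit PCM; multi-channel files return the first channel.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (!fmt$audio_format %in% c(1L, 65534L))
        stop("only PCM WAV is supported")
      bytes_per <- fmt$bits %/% 8L
      n_frames <- sz %/% (bytes_per * fmt$channels)
      if (fmt$bits == 16L) {
        pcm <- readBin(con, integer(), n = n_frames * fmt$channels,
                       size = 2, signed = TRUE, endian = "little")
        x <- pcm / 32768
      } else if (fmt$bits == 24L) {
        raw3 <- readBin(con, raw(), n = sz)
        m <- matrix(as.integer(raw3), nrow = 3)
        v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
        v <- ifelse(v >= 8388608, v - 16777216, v)
        x <- v / 8388608
      } else stop("unsupported bit depth: ", fmt$bits)
      if (fmt$channels > 1L)
        x <- x[seq(1L, length(x), by = fmt$channels)]
      return(list(samples = as.numeric(x), rate = fmt$rate))
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2))
    }
  }
}
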