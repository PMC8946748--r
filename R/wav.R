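# Minimal RIFF/WAVE PCM16 mono I/O. The recordings emulated here are plain
# 16-bit PCM; no compressed or multi-channel variants are supported.

#' Write a mono 16-bit PCM WAV file
#'
#' @param x Numeric waveform in sample units (full scale +-1). Values outside
#'   [-1, 1] are clamped (clipping), mirroring a recorder's ADC.
#' @param path Output file path.
#' @param fs_hz Sample rate, Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs_hz) {
  stopifnot(is.numeric(x), fs_hz > 0)
  x <- pmin(1, pmax(-1, x))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path File path.
#' @return A list with `x` (waveform scaled to full scale +-1) and `fs_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      if (fmt[2] != 1L) stop("only mono WAV supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      return(list(x = pcm / 32767, fs_hz = fs))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}
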