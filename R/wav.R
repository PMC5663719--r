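#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param x Numeric waveform in `[-1, 1]` (values outside are clipped).
#' @param sr Sample rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, sr, path) {
  stopifnot(is.numeric(x), sr > 0)
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF reader for files produced by [write_wav()] and other
#' uncompressed PCM recorders.
#'
#' @param path File path.
#' @return List with `wave` (numeric in `[-1, 1]`) and `sr` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only mono 16-bit PCM supported: ", path)
      }
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = sz - 8L))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2L, size = 2, signed = TRUE,
                     endian = "little")
      return(list(wave = pcm / 32767, sr = sr))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
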