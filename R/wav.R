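## Minimal PCM WAV I/O (16-bit mono), sufficient for breath-sound recordings.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and scaled to 16-bit integers.
#'
#' @param x numeric vector of samples in \[-1, 1\].
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, fs, path) {
  stopifnot(is.numeric(x), length(x) > 0, fs > 0)
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path, call. = FALSE)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) readBin(con, raw(), n = extra)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (bits != 16L || channels != 1L)
        stop("only 16-bit mono PCM WAV is supported", call. = FALSE)
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, raw(), n = size + (size %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  list(samples = samples / 32767, fs = fs)
}
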