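#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for mono 16-bit PCM, the format used for synthetic
#' call waveforms and preprocessed playback stimuli. Samples are expected in
#' [-1, 1]; values outside are clipped with a warning.
#'
#' @param samples Numeric vector of amplitudes in [-1, 1].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  if (any(abs(samples) > 1)) {
    warning("samples outside [-1, 1] clipped on write")
    samples <- pmax(pmin(samples, 1), -1)
  }
  pcm <- as.integer(round(samples * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]. Handles mono 16-bit PCM files and skips
#' non-data chunks. Samples are rescaled to [-1, 1] by 1/32767 so that a
#' write/read round trip reproduces in-range amplitudes to within one
#' quantisation step.
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric in [-1, 1]) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    chunk_id <- readChar(con, 4)
    if (length(chunk_id) == 0 || nchar(chunk_id) < 4) stop("no data chunk found in ", path)
    chunk_size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(chunk_id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      if (fmt[2] != 1L) stop("only mono WAV supported")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      bits <- readBin(con, "integer", n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit WAV supported")
      if (chunk_size > 16) invisible(readBin(con, "raw", n = chunk_size - 16L))
    } else if (identical(chunk_id, "data")) {
      if (is.null(sample_rate)) stop("data chunk precedes fmt chunk in ", path)
      pcm <- readBin(con, "integer", n = chunk_size / 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", n = chunk_size))
    }
  }
}
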