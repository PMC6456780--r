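# Minimal RIFF/WAVE writer and reader for mono IEEE-float-32 PCM, used for
# stimulus audio. Only the canonical fmt/data chunk layout is supported.

#' Write / read a mono float-PCM WAV file
#'
#' @param samples Numeric vector (linear amplitude).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output path.
#' @return `write_wav()` returns the path invisibly; `read_wav()` a list with
#'   `samples` and `sample_rate_hz`.
#' @export
write_wav <- function(samples, sample_rate_hz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")   # block align
  writeBin(32L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  stop_if_not(file.exists(path), "WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  stop_if_not(identical(riff, "RIFF") && identical(wave, "WAVE"),
              "not a RIFF/WAVE file: %s", path)
  fs <- NULL
  fmt_code <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8L)
    } else if (identical(id, "data")) {
      stop_if_not(identical(fmt_code, 3L), "only float-PCM WAV supported")
      x <- readBin(con, numeric(), n = sz %/% 4L, size = 4, endian = "little")
      return(list(samples = x, sample_rate_hz = fs))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
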