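#' Write a mono WAV file (IEEE float32)
#'
#' @param samples Numeric vector.
#' @param rate Sampling rate, Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, single channel.
#'
#' @param path WAV file path.
#' @return List with `samples` and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; rate <- NULL; bits <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt in ", path)
      if (channels != 1) stop("only mono WAV supported")
      n <- size / (bits / 8)
      samples <- if (fmt == 3 && bits == 32) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else if (fmt == 1 && bits == 16) {
        readBin(con, integer(), n = n, size = 2, signed = TRUE,
                endian = "little") / 32768
      } else stop("unsupported WAV encoding (fmt ", fmt, ", ", bits, " bit)")
      return(list(samples = samples, rate = rate))
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
  }
}
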