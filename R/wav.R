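# Minimal RIFF/WAVE reader and writer (PCM16 and IEEE float32), enough for
# the package's audio interchange: multi-channel, 16 kHz, float32 by default.

#' Write audio to a WAV file
#'
#' @param x numeric vector (mono) or samples-by-channels matrix, full scale
#'   +-1.0
#' @param path output file path
#' @param fs sampling rate in Hz
#' @param format `"float32"` (default) or `"pcm16"`
#' @export
write_wav <- function(x, path, fs = FS, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n_ch <- ncol(x)
  n <- nrow(x)
  interleaved <- as.numeric(t(x))
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- if (format == "float32") 4L else 2L
  fmt_code <- if (format == "float32") 3L else 1L
  data_bytes <- n * n_ch * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * n_ch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path file path
#' @return list with `x` (samples-by-channels matrix, float in +-1.0) and
#'   `fs` (Hz)
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a RIFF/WAVE file")
  fmt_code <- NA_integer_; n_ch <- NA_integer_; fs <- NA_integer_
  bits <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_ch <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      if (fmt_code == 3 && bits == 32) {
        raw <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      } else if (fmt_code == 1 && bits == 16) {
        raw <- readBin(con, "integer", sz / 2, size = 2,
                       endian = "little") / 32767
      } else {
        stop("unsupported WAV format (need float32 or pcm16)")
      }
      return(list(x = matrix(raw, ncol = n_ch, byrow = TRUE), fs = fs))
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
  }
}
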