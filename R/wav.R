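# Minimal RIFF/WAVE I/O (PCM16 and IEEE float32, mono). Kept self-contained:
# byte layout is fixed little-endian per the RIFF specification.

#' Write a waveform to a WAV file
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @param format `"float32"` (IEEE float, values written as-is) or
#'   `"pcm16"` (samples are peak-normalized to 0.999 before quantization).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  stopifnot(inherits(w, "waveform"))
  fs <- as.integer(round(w$sample_rate))
  x <- w$samples
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    x <- x / max(abs(x)) * 0.999
    data <- writeBin(integer(0), raw())
    samples <- as.integer(round(x * 32767))
    bits <- 16L; fmt_code <- 1L; bytes_per <- 2L
  } else {
    bits <- 32L; fmt_code <- 3L; bytes_per <- 4L
  }
  n_data <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_data), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(samples, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' Supports PCM16 and IEEE float32, single channel.
#'
#' @param path WAV file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop_input("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop_input("not a WAVE file")
  fmt_code <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_input("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (n_chan != 1L) stop_input("only mono WAV supported")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (id == "data") {
      if (is.null(fmt_code)) stop_input("data chunk before fmt chunk")
      if (fmt_code == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
      } else {
        stop_input("unsupported WAV format code ", fmt_code, "/", bits, " bit")
      }
      return(new_waveform(x, fs))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
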