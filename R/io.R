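#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE reader and writer for mono recordings (no audio
#' package ships with the dependency set, and only two encodings are
#' needed): 32-bit IEEE float, which round-trips normalized samples
#' losslessly, and 16-bit PCM, exact to one quantization step. Multichannel
#' files and other encodings are rejected.
#'
#' @param path File path.
#' @param w A `croaker_waveform`. Samples are written as-is for
#'   `"float32"`; for `"pcm16"` they must lie in `[-1, 1]` and are scaled to
#'   the 16-bit range.
#' @param encoding `"float32"` or `"pcm16"`.
#' @param unit Unit tag attached to the waveform on read.
#' @return `read_wav()`: a `croaker_waveform`. `write_wav()`: `path`,
#'   invisibly.
#' @export
write_wav <- function(w, path, encoding = c("float32", "pcm16")) {
  encoding <- match.arg(encoding)
  w <- as_waveform(w)
  x <- w$samples
  fs <- as.integer(round(w$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  if (encoding == "float32") {
    fmt_code <- 3L; bits <- 32L
    data_size <- 4L * length(x)
  } else {
    if (max(abs(x)) > 1 + 1e-12) {
      abort("pcm16 encoding requires samples in [-1, 1]")
    }
    fmt_code <- 1L; bits <- 16L
    data_size <- 2L * length(x)
  }
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block), con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (encoding == "float32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmin(pmax(round(x * 32767), -32768), 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path, unit = "normalized") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) abort("not a RIFF/WAVE file")
  fmt_code <- NULL; channels <- NULL; fs <- NULL; bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16L)
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) abort("malformed WAV: data before fmt")
      if (channels != 1L) abort("only mono WAV files are supported")
      if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", sz %/% 4L, size = 4,
                           endian = "little")
      } else if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", sz %/% 2L, size = 2,
                           endian = "little", signed = TRUE) / 32767
      } else {
        abort("unsupported WAV encoding (need float32 or pcm16)")
      }
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) abort("malformed WAV: no data chunk")
  waveform(samples, fs, unit)
}
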