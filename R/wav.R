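#' Read a mono waveform from a RIFF WAV file
#'
#' Supports uncompressed 16-bit PCM (format tag 1) and 32-bit IEEE float
#' (format tag 3). Samples are returned as doubles in `[-1, 1]` (PCM data is
#' divided by 32767). Multi-channel files require an explicit `channel`
#' selection; silently mixing channels would hide a recording-setup error.
#'
#' @param path Path to a `.wav` file.
#' @param channel 1-based channel index to extract from a multi-channel file.
#'   Ignored (may stay `NULL`) for mono input.
#' @param expect_rate If non-`NULL`, the sample rate (Hz) the caller requires.
#' @param on_rate_mismatch What to do when the file's rate differs from
#'   `expect_rate`: `"error"` (default) or `"resample"` (linear
#'   interpolation to `expect_rate`).
#' @return A list with `waveform` (numeric vector), `sample_rate` (Hz) and
#'   `encoding` (`"pcm16"` or `"float32"`).
#' @export
read_wav <- function(path, channel = NULL, expect_rate = NULL,
                     on_rate_mismatch = c("error", "resample")) {
  on_rate_mismatch <- match.arg(on_rate_mismatch)
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # total size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        rate     = readBin(con, "integer", 1, size = 4, endian = "little"),
        byterate = readBin(con, "integer", 1, size = 4, endian = "little"),
        align    = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits     = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      extra <- sz - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)  # chunk padding
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) / 2L, size = 2,
                 signed = TRUE, endian = "little") / 32767
    encoding <- "pcm16"
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n = length(data_raw) / 4L, size = 4,
                 endian = "little")
    encoding <- "float32"
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$format, ", ",
         fmt$bits, " bits); only 16-bit PCM and 32-bit float are handled")
  }

  if (fmt$channels > 1L) {
    if (is.null(channel)) {
      stop("file has ", fmt$channels,
           " channels; pass `channel = <index>` to select one")
    }
    if (channel < 1 || channel > fmt$channels) stop("channel out of range")
    x <- x[seq(channel, length(x), by = fmt$channels)]
  }

  rate <- fmt$rate
  if (!is.null(expect_rate) && rate != expect_rate) {
    if (on_rate_mismatch == "error") {
      stop("sample rate ", rate, " Hz does not match required ", expect_rate,
           " Hz; pass on_rate_mismatch = \"resample\" to convert")
    }
    n_out <- round(length(x) * expect_rate / rate)
    x <- stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
    rate <- expect_rate
  }

  list(waveform = x, sample_rate = rate, encoding = encoding)
}

#' Write a mono waveform to a RIFF WAV file
#'
#' @param path Output path.
#' @param waveform Numeric vector of samples, nominally in `[-1, 1]` (clipped
#'   for PCM output).
#' @param sample_rate Sample rate in Hz.
#' @param encoding `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, waveform, sample_rate, encoding = c("pcm16", "float32")) {
  encoding <- match.arg(encoding)
  stopifnot(is.numeric(waveform), length(waveform) > 0, sample_rate > 0)
  con <- file(path, "wb")
  on.exit(close(con))

  n <- length(waveform)
  if (encoding == "pcm16") {
    bits <- 16L; tag <- 1L
    bytes <- 2L * n
  } else {
    bits <- 32L; tag <- 3L
    bytes <- 4L * n
  }
  block <- as.integer(bits / 8L)

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                    # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block), con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes), con, size = 4, endian = "little")

  if (encoding == "pcm16") {
    q <- as.integer(round(pmin(pmax(waveform, -1), 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.double(waveform), con, size = 4, endian = "little")
  }
  invisible(path)
}
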