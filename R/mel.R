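# STFT and mel filterbank. No audio-analysis package ships with base R, so
# the transform is implemented here directly: centred Hann-windowed frames,
# magnitude FFT, Slaney-style triangular mel filters with area
# normalization.

.vibrotemp_cache <- new.env(parent = emptyenv())

hz_to_mel <- function(f) {
  ifelse(f < 1000, 3 * f / 200, 15 + 27 * log(f / 1000) / log(6.4))
}

mel_to_hz <- function(m) {
  ifelse(m < 15, 200 * m / 3, 1000 * exp(log(6.4) * (m - 15) / 27))
}

#' Mel filterbank matrix
#'
#' `n_mels` triangular filters on the Slaney mel scale (linear below 1 kHz,
#' logarithmic above) spanning `[fmin, fmax]`, with each triangle scaled by
#' `2 / bandwidth` (area normalization).
#'
#' @param sample_rate Sample rate in Hz.
#' @param fft_size FFT length.
#' @param n_mels Number of mel filters.
#' @param fmin,fmax Frequency range in Hz.
#' @return Matrix of size `n_mels x (fft_size/2 + 1)`.
#' @export
mel_filterbank <- function(sample_rate, fft_size = 2048L, n_mels = 256L,
                           fmin = 1, fmax = 20000) {
  key <- paste(sample_rate, fft_size, n_mels, fmin, fmax, sep = "_")
  cached <- .vibrotemp_cache[[key]]
  if (!is.null(cached)) return(cached)

  n_bins <- fft_size %/% 2L + 1L
  bin_hz <- (0:(n_bins - 1L)) * sample_rate / fft_size
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                       length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    dn <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn)) * 2 / (hi - lo)
  }
  .vibrotemp_cache[[key]] <- fb
  fb
}

# Centred magnitude STFT: the signal is zero-padded by fft_size/2 on both
# sides, so frame k is centred on sample (k-1)*hop and the frame count is
# 1 + floor(n / hop).
stft_power <- function(x, fft_size = 2048L, hop = 512L) {
  n <- length(x)
  n_frames <- 1L + n %/% hop
  half <- fft_size %/% 2L
  xp <- c(numeric(half), x, numeric(fft_size - half))
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(fft_size), starts, "+")
  frames <- matrix(xp[idx], fft_size, n_frames)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(fft_size - 1L)) / fft_size)
  spec <- stats::mvfft(frames * win)
  Mod(spec[seq_len(half + 1L), , drop = FALSE])^2
}

#' Mel spectrogram of a waveform chunk
#'
#' Power STFT with centred frames projected onto the mel filterbank and
#' converted to decibels relative to the chunk's maximum mel energy, floored
#' at `floor_db`. Scaling to the per-chunk maximum makes the features
#' gain-invariant; an all-zero chunk maps to a spectrogram uniformly at the
#' floor.
#'
#' @param x Numeric waveform (a chunk's samples), or a `chunk` object.
#' @param sample_rate Sample rate in Hz (taken from the chunk if omitted).
#' @param fft_size FFT length (default 2048).
#' @param hop Hop length in samples (default 512).
#' @param n_mels Number of mel bins (default 256).
#' @param fmin,fmax Analysis band in Hz (defaults 1 Hz to 20 kHz).
#' @param floor_db dB floor (default -80).
#' @return A `mel_spec` object whose `values` matrix is
#'   `n_mels x n_frames`, in dB.
#' @export
mel_spectrogram <- function(x, sample_rate = NULL, fft_size = 2048L,
                            hop = 512L, n_mels = 256L, fmin = 1,
                            fmax = 20000, floor_db = -80) {
  if (inherits(x, "chunk")) {
    if (is.null(sample_rate)) sample_rate <- x$sample_rate
    x <- x$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  if (length(x) < 1) stop("empty chunk")
  if (sample_rate < 2 * fmax) {
    stop("sample_rate ", sample_rate, " Hz below 2*fmax = ", 2 * fmax, " Hz")
  }

  pw <- stft_power(x, fft_size, hop)
  fb <- mel_filterbank(sample_rate, fft_size, n_mels, fmin, fmax)
  S <- fb %*% pw
  ref <- max(S)
  if (ref <= 0) {
    vals <- matrix(floor_db, n_mels, ncol(S))
  } else {
    vals <- 10 * log10(S / ref)
    vals[!is.finite(vals)] <- floor_db
    vals <- pmax(vals, floor_db)
  }
  structure(list(values = vals, sample_rate = sample_rate,
                 fft_size = fft_size, hop = hop, n_mels = n_mels,
                 fmin = fmin, fmax = fmax, floor_db = floor_db),
            class = "mel_spec")
}

#' @export
print.mel_spec <- function(x, ...) {
  cat(sprintf("<mel_spec> %d mel bins x %d frames | %g-%g Hz, fft %d, hop %d\n",
              nrow(x$values), ncol(x$values), x$fmin, x$fmax,
              x$fft_size, x$hop))
  invisible(x)
}

#' Spectral centroid of a waveform
#'
#' First moment of the magnitude spectrum, in Hz. Used as the independent
#' check that the injected temperature effect shifts event spectra.
#'
#' @param x Numeric waveform.
#' @param sample_rate Sample rate in Hz.
#' @return Centroid frequency in Hz (0 for an all-zero input).
#' @export
spectral_centroid <- function(x, sample_rate) {
  mag <- Mod(stats::fft(x))[seq_len(length(x) %/% 2 + 1)]
  if (sum(mag) <= 0) return(0)
  freqs <- (seq_along(mag) - 1) * sample_rate / length(x)
  sum(freqs * mag) / sum(mag)
}
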