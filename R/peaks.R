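#' Envelope smoothing parameters
#'
#' The envelope is the rectified waveform passed repeatedly through a short
#' uniform (boxcar) averaging filter. The defaults -- a 20-tap filter applied
#' 4 times -- merge the sub-millisecond oscillation of an individual event
#' into a single smooth hump while leaving distinct bubble events separate.
#'
#' @param taps Length of the uniform averaging kernel (>= 1).
#' @param passes Number of times the kernel is applied (>= 1).
#' @return An `envelope_params` object.
#' @export
envelope_params <- function(taps = 20L, passes = 4L) {
  stopifnot(taps >= 1, passes >= 1)
  structure(list(taps = as.integer(taps), passes = as.integer(passes)),
            class = "envelope_params")
}

#' Smoothed envelope of a waveform
#'
#' Rectifies the signal and convolves it `passes` times with a length-`taps`
#' uniform kernel (each weight `1/taps`), using zero-padded, length-preserving
#' ("same") convolution so peak times stay aligned with the annotations.
#'
#' @param waveform Non-empty numeric vector.
#' @param params An [envelope_params()].
#' @return Non-negative numeric vector, same length as `waveform`.
#' @export
smooth_envelope <- function(waveform, params = envelope_params()) {
  if (length(waveform) == 0) stop("empty waveform")
  env <- abs(waveform)
  for (p in seq_len(params$passes)) {
    env <- boxcar_same(env, params$taps)
  }
  env
}

# "same" moving average: output[i] = mean(xpad[i - c .. i - c + taps - 1])
# with c = floor((taps - 1) / 2) and zero padding. Accumulation order over
# the taps is the natural j = 1..taps order.
boxcar_same <- function(x, taps) {
  n <- length(x)
  cshift <- (taps - 1L) %/% 2L
  xp <- c(numeric(cshift), x, numeric(taps - 1L - cshift))
  acc <- numeric(n)
  for (j in seq_len(taps)) {
    acc <- acc + xp[j:(j + n - 1L)]
  }
  acc / taps
}

#' Detect envelope peaks with a mean-plus-sigma threshold
#'
#' Candidate peaks are all interior local maxima of the envelope (strict
#' rise into the sample, non-strict fall after it, so the first sample of a
#' flat plateau counts). Their amplitudes mix background-noise maxima
#' (clustered near the mean) with true needle-bubble events (far above it),
#' so peaks are retained when their amplitude reaches
#' `theta = mu + sigma`, one standard deviation above the mean candidate
#' amplitude of this recording.
#'
#' @param envelope Non-negative numeric vector (see [smooth_envelope()]).
#' @param sample_rate Sample rate in Hz.
#' @param sigma `"population"` (default) or `"sample"` standard deviation
#'   convention for the candidate amplitudes.
#' @return A `peak_list`: `times` (s), `amplitudes`, `mu`, `sigma`, `theta`,
#'   `n_candidates`, plus the `sample_rate` and convention used. Zero
#'   candidates yield an empty list with `mu = sigma = theta = 0`.
#' @export
detect_peaks <- function(envelope, sample_rate, sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  if (length(envelope) < 3) stop("need at least 3 samples to detect peaks")
  if (any(envelope < 0)) stop("envelope must be non-negative")

  n <- length(envelope)
  i <- 2:(n - 1L)
  is_max <- envelope[i] > envelope[i - 1L] & envelope[i] >= envelope[i + 1L]
  cand <- i[is_max]
  amps <- envelope[cand]

  if (length(amps) == 0) {
    return(structure(list(times = numeric(0), amplitudes = numeric(0),
                          mu = 0, sigma = 0, theta = 0, n_candidates = 0L,
                          sample_rate = sample_rate, sigma_type = sigma),
                     class = "peak_list"))
  }
  mu <- mean(amps)
  sg <- if (sigma == "population") {
    sqrt(mean((amps - mu)^2))
  } else {
    if (length(amps) > 1) stats::sd(amps) else 0
  }
  theta <- mu + sg
  keep <- amps >= theta
  structure(list(times = (cand[keep] - 1) / sample_rate,
                 amplitudes = amps[keep],
                 mu = mu, sigma = sg, theta = theta,
                 n_candidates = length(amps),
                 sample_rate = sample_rate, sigma_type = sigma),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf(
    "<peak_list> %d retained / %d candidates | mu=%.4g sigma=%.4g theta=%.4g (%s)\n",
    length(x$times), x$n_candidates, x$mu, x$sigma, x$theta, x$sigma_type))
  invisible(x)
}

#' Peak density along the needle path
#'
#' Converts a peak count inside a time window into events per centimetre of
#' needle travel, the quantity compared against the foam's known bubble
#' density.
#'
#' @param peaks A `peak_list`.
#' @param window Two-element numeric `c(t_start, t_end)` in seconds.
#' @param speed Needle speed in mm/s during the window.
#' @return Peaks per cm (numeric scalar).
#' @export
peak_rate <- function(peaks, window, speed) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) stop("window must satisfy t_end > t_start")
  if (speed <= 0) stop("speed must be positive")
  dist_cm <- speed * (window[2] - window[1]) / 10
  if (dist_cm <= 0) stop("zero travel distance")
  n_in <- sum(peaks$times >= window[1] & peaks$times <= window[2])
  n_in / dist_cm
}
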