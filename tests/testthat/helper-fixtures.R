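# Shared fixtures and independent brute-force oracles.

# A bare annotated recording with hand-set annotations (no simulation).
make_recording <- function(waveform, sample_rate = 48000, L1 = 0.5, L2 = 1.0,
                           L3 = 1.2, L4 = 1.7, temperature = 35,
                           id = "fix_01") {
  structure(list(waveform = waveform, sample_rate = sample_rate,
                 L1 = L1, L2 = L2, L3 = L3, L4 = L4,
                 temperature_group = temperature,
                 measured_temperature = temperature,
                 true_event_times = numeric(0),
                 speed_mm_s = 7, recording_id = id),
            class = "annotated_recording")
}

# A quick short simulated insertion for pipeline tests.
quick_insertion <- function(seed, temperature = 35, density = 20,
                            thickness = 1, speed = 8) {
  set.seed(seed)
  simulate_insertion(foam_spec(density, thickness),
                     insertion_profile(speed = speed),
                     temperature, temperature_effect(), synth_config())
}

# Loop-based envelope oracle: per-sample window means, zero padded,
# repeated `passes` times. Written independently of the package internals.
brute_envelope <- function(x, taps = 20, passes = 4) {
  env <- abs(x)
  n <- length(env)
  cshift <- floor((taps - 1) / 2)
  for (p in seq_len(passes)) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(taps)) {
        src <- i + (j - 1) - cshift
        if (src >= 1 && src <= n) acc <- acc + env[src]
      }
      out[i] <- acc / taps
    }
    env <- out
  }
  env
}

# Loop-based peak detector oracle mirroring the documented conventions:
# interior maxima with strict rise / non-strict fall, population sigma.
brute_detect <- function(env, sample_rate) {
  idx <- integer(0)
  for (i in 2:(length(env) - 1)) {
    if (env[i] > env[i - 1] && env[i] >= env[i + 1]) idx <- c(idx, i)
  }
  amps <- env[idx]
  if (length(amps) == 0) {
    return(list(times = numeric(0), amplitudes = numeric(0),
                mu = 0, sigma = 0, theta = 0, n_candidates = 0L))
  }
  mu <- sum(amps) / length(amps)
  sigma <- sqrt(sum((amps - mu)^2) / length(amps))
  theta <- mu + sigma
  keep <- which(amps >= theta)
  list(times = (idx[keep] - 1) / sample_rate, amplitudes = amps[keep],
       mu = mu, sigma = sigma, theta = theta, n_candidates = length(amps))
}

# Direct DFT spectral centroid (independent of the package's FFT helper).
dft_centroid <- function(x, sample_rate) {
  n <- length(x)
  half <- n %/% 2 + 1
  mags <- vapply(seq_len(half), function(k) {
    w <- -2i * pi * (k - 1) * (seq_len(n) - 1) / n
    Mod(sum(x * exp(w)))
  }, numeric(1))
  freqs <- (seq_len(half) - 1) * sample_rate / n
  sum(freqs * mags) / sum(mags)
}

# Random noise chunks for training-plumbing tests (not from a simulation).
noise_chunks <- function(n_rec, per_rec, label_fn, len = 480,
                         sample_rate = 48000) {
  out <- list()
  for (r in seq_len(n_rec)) {
    for (k in seq_len(per_rec)) {
      out[[length(out) + 1L]] <- structure(
        list(samples = stats::rnorm(len, 0, 0.01), sample_rate = sample_rate,
             recording_id = sprintf("nr%02d", r),
             center_time = k * 0.1, label = label_fn(r),
             source = "peak_centered", peak_offset = 0L),
        class = "chunk")
    }
  }
  out
}
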