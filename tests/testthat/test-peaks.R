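test_that("envelope smoothing matches its definition on an impulse", {
  x <- numeric(401)
  x[200] <- 1
  one_pass <- smooth_envelope(x, envelope_params(taps = 20, passes = 1))
  plateau <- which(abs(one_pass - 1 / 20) < 1e-12)
  expect_length(plateau, 20)
  expect_true(all(one_pass[-plateau] == 0))

  four <- smooth_envelope(x, envelope_params(taps = 20, passes = 4))
  oracle <- brute_envelope(x, 20, 4)
  expect_equal(four, oracle, tolerance = 1e-12)
  # support of the 4-fold self-convolution of a length-20 kernel: 4*20-3
  expect_equal(sum(four > 0), 4 * 20 - 3)
  expect_equal(max(four), max(oracle))
})

test_that("envelope is rectification-symmetric, length-preserving and scale-equivariant", {
  expect_equal(smooth_envelope(numeric(100)), numeric(100))
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(200 + s * 37)
    e <- smooth_envelope(x)
    expect_length(e, length(x))
    expect_true(all(e >= 0))
    expect_equal(e, smooth_envelope(-x))
    expect_equal(smooth_envelope(2.5 * x), 2.5 * e, tolerance = 1e-12)
  }
  expect_error(smooth_envelope(numeric(0)), "empty")
})

test_that("the worked five-candidate threshold example retains one peak under both sigma conventions", {
  env <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 10, 0)
  pop <- detect_peaks(env, 1, sigma = "population")
  expect_equal(pop$n_candidates, 5L)
  expect_equal(pop$mu, 2.8)
  expect_equal(pop$sigma, 3.6)
  expect_equal(pop$theta, 6.4)
  expect_equal(pop$amplitudes, 10)

  sam <- detect_peaks(env, 1, sigma = "sample")
  expect_equal(sam$sigma, sd(c(1, 1, 1, 1, 10)))
  expect_equal(sam$theta, sam$mu + sam$sigma)
  expect_equal(sam$amplitudes, 10)
})

test_that("degenerate envelopes are handled per contract", {
  expect_length(detect_peaks(seq(0, 1, length.out = 50), 48000)$times, 0)
  mono <- detect_peaks(seq(0, 1, length.out = 50), 48000)
  expect_equal(c(mono$mu, mono$sigma, mono$theta), c(0, 0, 0))
  expect_error(detect_peaks(c(1, 2), 48000), "3 samples")
  expect_error(detect_peaks(c(1, -1, 1, 0), 48000), "non-negative")
})

test_that("detector threshold contract holds exactly on random envelopes", {
  for (s in 1:10) {
    set.seed(s)
    env <- smooth_envelope(rnorm(2000))
    pk <- detect_peaks(env, 48000)
    expect_identical(pk$theta, pk$mu + pk$sigma)
    if (length(pk$amplitudes) > 0) {
      expect_gte(min(pk$amplitudes), pk$theta)
      expect_true(all(diff(pk$times) > 0))
    }
  }
})

test_that("vectorized detector agrees exactly with the loop-based oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(50:1000, 1)
    x <- rnorm(n)
    env <- smooth_envelope(x)
    expect_equal(env, brute_envelope(x), tolerance = 1e-12)
    pk <- detect_peaks(env, 48000)
    or <- brute_detect(env, 48000)
    expect_identical(pk$times, or$times)
    expect_identical(pk$amplitudes, or$amplitudes)
    expect_equal(pk$mu, or$mu)
    expect_equal(pk$sigma, or$sigma)
    expect_equal(pk$n_candidates, or$n_candidates)
  }
})

test_that("peak_rate converts window counts to events per centimetre", {
  empty <- structure(list(times = numeric(0)), class = "peak_list")
  expect_equal(peak_rate(empty, c(0, 1), 7), 0)

  pk <- structure(list(times = seq(0.05, 2.95, length.out = 30)),
                  class = "peak_list")
  # 30 peaks over 3 s at 5 mm/s -> 1.5 cm of travel -> 20 peaks/cm
  expect_equal(peak_rate(pk, c(0, 3), 5), 20)
  expect_error(peak_rate(pk, c(1, 1), 5), "t_end > t_start")
  expect_error(peak_rate(pk, c(0, 1), 0), "speed")
})

test_that("detected density tracks the configured density and is speed-invariant", {
  rates <- sapply(c(5, 10), function(speed) {
    mean(sapply(1:3, function(s) {
      set.seed(100 + 7 * s + speed)
      rec <- simulate_insertion(foam_spec(12, 2),
                                insertion_profile(speed = speed), 35,
                                temperature_effect(), synth_config())
      pk <- detect_peaks(smooth_envelope(rec$waveform), rec$sample_rate)
      peak_rate(pk, c(rec$L1, rec$L2), speed)
    }))
  })
  expect_true(all(abs(rates - 12) / 12 < 0.1))
  expect_lt(abs(rates[1] - rates[2]) / 12, 0.1)
})
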