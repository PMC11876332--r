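test_that("event bursts are zero at zero amplitude and identical without an effect", {
  eff0 <- temperature_effect(amplitude = 0)
  set.seed(1)
  expect_equal(event_waveform(30, eff0, 48000), rep(0, round(0.008 * 48000)))

  flat <- temperature_effect(slope = 0, decay_slope = 0)
  set.seed(5)
  b25 <- event_waveform(25, flat, 48000)
  set.seed(5)
  b55 <- event_waveform(55, flat, 48000)
  expect_identical(b25, b55)
})

test_that("a positive frequency slope shifts the burst spectral centroid upward", {
  eff <- temperature_effect(slope = 50)
  set.seed(2)
  cold <- event_waveform(25, eff, 48000)
  set.seed(2)
  hot <- event_waveform(55, eff, 48000)
  expect_gt(dft_centroid(hot, 48000), dft_centroid(cold, 48000))
})

test_that("non-positive decay constants are rejected", {
  eff <- temperature_effect(decay_tau = 0.002, decay_slope = -0.001)
  expect_error(event_waveform(25, eff, 48000), "decay")
})

test_that("forward event count and timing follow density, thickness and speed", {
  set.seed(3)
  rec <- simulate_insertion(foam_spec(20, 3), insertion_profile(speed = 6),
                            35, temperature_effect(), synth_config())
  fwd <- rec$true_event_times[rec$true_event_times <= rec$L2]
  expect_length(fwd, 60)
  expect_equal(rec$L2 - rec$L1, 30 / 6)
  expect_true(all(fwd > rec$L1 & fwd < rec$L2))
  ret <- rec$true_event_times[rec$true_event_times > rec$L2]
  expect_length(ret, 60)
  expect_true(all(ret > rec$L3 & ret < rec$L4))
})

test_that("zero bubble density produces an event-free recording", {
  set.seed(4)
  rec <- simulate_insertion(foam_spec(0, 3), insertion_profile(speed = 8),
                            35, temperature_effect(), synth_config())
  expect_length(rec$true_event_times, 0)
})

test_that("the raw-signal envelope shows the insertion phase structure", {
  set.seed(6)
  rec <- simulate_insertion(foam_spec(20, 2), insertion_profile(speed = 8),
                            40, temperature_effect(), synth_config())
  env <- smooth_envelope(rec$waveform)
  sr <- rec$sample_rate
  # events are sparse bursts, so compare upper-quantile envelope activity
  seg_q <- function(a, b) quantile(env[round(a * sr):round(b * sr)], 0.99)
  quiet_approach <- seg_q(rec$L1 - 0.8, rec$L1 - 0.1)
  forward <- seg_q(rec$L1, rec$L2)
  dwell <- seg_q(rec$L2 + 0.1, rec$L3 - 0.1)
  retract <- seg_q(rec$L3, rec$L4)
  pulse_peak <- max(env[seq_len(round(rec$L1 * sr))])
  expect_gt(forward, 2 * quiet_approach)
  expect_gt(retract, 2 * dwell)
  expect_gt(pulse_peak, max(env[round(rec$L1 * sr):round(rec$L2 * sr)]))
})

test_that("annotation ordering holds for every generated recording", {
  cfg <- synth_config(seed = 9, temp_groups = c(20, 40, 55),
                      recordings_per_group = 2)
  ds <- generate_dataset(cfg, foam = foam_spec(15, 1),
                         speed_range = c(5, 10))
  for (rec in ds$recordings) {
    expect_true(0 < rec$L1 && rec$L1 < rec$L2 && rec$L2 <= rec$L3 &&
                  rec$L3 < rec$L4)
    dur <- length(rec$waveform) / rec$sample_rate
    expect_lt(rec$L4, dur)
    ok <- (rec$true_event_times >= rec$L1 & rec$true_event_times <= rec$L2) |
      (rec$true_event_times >= rec$L3 & rec$true_event_times <= rec$L4)
    expect_true(all(ok))
  }
})

test_that("default configuration yields 8 groups x 22 recordings", {
  out <- withr::local_tempdir()
  cfg <- synth_config(seed = 2)
  ds <- generate_dataset(cfg, foam = foam_spec(10, 0.5),
                         speed_range = c(7, 10), out_dir = out)
  expect_equal(nrow(ds$manifest), 176)
  expect_equal(sort(unique(ds$manifest$temperature_group)), seq(20, 55, 5))
  expect_equal(unname(table(ds$manifest$temperature_group)[1]), 22)
  expect_length(list.files(out, pattern = "\\.wav$"), 176)
  # cooldown drift: measured below nominal, within the scaled ceiling
  off <- ds$manifest$temperature_group - ds$manifest$measured_temperature
  expect_true(all(off >= 0 & off <= 1.4))
  hot <- off[ds$manifest$temperature_group == 55]
  cold <- off[ds$manifest$temperature_group == 20]
  expect_true(max(hot) > max(cold))
})

test_that("zero recordings per group yields an empty manifest and no files", {
  out <- withr::local_tempdir()
  cfg <- synth_config(seed = 3, recordings_per_group = 0)
  ds <- generate_dataset(cfg, out_dir = out)
  expect_equal(nrow(ds$manifest), 0)
  expect_length(list.files(out), 0)
})

test_that("empty temperature groups are rejected", {
  cfg <- synth_config(seed = 3)
  cfg$temp_groups <- numeric(0)
  expect_error(generate_dataset(cfg), "non-empty")
})

test_that("regeneration under a fixed seed is byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synth_config(seed = 17, temp_groups = c(25, 50),
                      recordings_per_group = 2)
  generate_dataset(cfg, foam = foam_spec(10, 0.5), out_dir = d1)
  generate_dataset(cfg, foam = foam_spec(10, 0.5), out_dir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in setdiff(f1, "manifest.csv")) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
  # manifests agree except for the output-directory-dependent path columns
  m1 <- read_manifest(file.path(d1, "manifest.csv"))
  m2 <- read_manifest(file.path(d2, "manifest.csv"))
  drop <- c("audio_path", "annotation_path")
  expect_identical(m1[setdiff(names(m1), drop)], m2[setdiff(names(m2), drop)])
})

test_that("event spectral centroids rise monotonically across temperature groups", {
  groups <- c(20, 30, 45, 55)
  cents <- vapply(groups, function(g) {
    per_rec <- vapply(1:10, function(s) {
      set.seed(1000 * g + s)
      rec <- simulate_insertion(foam_spec(10, 1),
                                insertion_profile(speed = 10), g,
                                temperature_effect(), synth_config())
      sr <- rec$sample_rate
      ev <- rec$true_event_times[rec$true_event_times <= rec$L2]
      cs <- vapply(ev, function(tt) {
        seg <- rec$waveform[round(tt * sr) + 1:384]
        spectral_centroid(seg, sr)
      }, numeric(1))
      mean(cs)
    }, numeric(1))
    mean(per_rec)
  }, numeric(1))
  expect_true(all(diff(cents) > 0))
})
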