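test_that("sliding chunk counts match the closed form and overlap is 25%", {
  sr <- 48000
  # 18,000-sample window: floor((18000 - 4800)/3600) + 1 = 4 chunks
  rec <- make_recording(rnorm(sr), sr, L1 = 0.1, L2 = 0.1 + 18000 / sr,
                        L3 = 0.6, L4 = 0.9)
  ch <- slice_sliding(rec)
  expect_length(ch, 4)
  expect_true(all(vapply(ch, function(c) length(c$samples), numeric(1)) == 4800))
  # consecutive chunks share exactly 25% of their samples
  expect_identical(ch[[1]]$samples[3601:4800], ch[[2]]$samples[1:1200])
  expect_identical(ch[[2]]$samples[3601:4800], ch[[3]]$samples[1:1200])
  # closed form over varying window lengths
  for (n_samp in c(4800, 5000, 9600, 12345)) {
    rec2 <- make_recording(rnorm(sr), sr, L1 = 0.1, L2 = 0.1 + n_samp / sr,
                           L3 = 0.6, L4 = 0.9)
    expect_length(slice_sliding(rec2), (n_samp - 4800) %/% 3600 + 1)
  }
})

test_that("windows shorter than one chunk yield no sliding chunks", {
  sr <- 48000
  rec <- make_recording(rnorm(sr), sr, L1 = 0.1, L2 = 0.19, L3 = 0.3, L4 = 0.5)
  expect_length(slice_sliding(rec), 0)
})

test_that("chunks carry their source recording id and label", {
  rec <- quick_insertion(21, temperature = 42.5)
  pk <- detect_peaks(smooth_envelope(rec$waveform), rec$sample_rate)
  set.seed(1)
  ch <- slice_peak_centered(rec, pk)
  idx <- chunk_index(ch)
  expect_true(all(idx$recording_id == rec$recording_id))
  expect_true(all(idx$label == 42.5))
  expect_true(all(idx$source == "peak_centered"))
})

test_that("zero jitter puts the peak sample exactly at the chunk centre", {
  sr <- 48000
  wav <- rnorm(sr, 0, 0.001)
  p_idx <- c(12000, 20000, 30000)
  wav[p_idx] <- 5
  rec <- make_recording(wav, sr, L1 = 0.01, L2 = 0.9, L3 = 0.92, L4 = 0.99)
  pk <- structure(list(times = (p_idx - 1) / sr, sample_rate = sr),
                  class = "peak_list")
  ch <- slice_peak_centered(rec, pk, jitter_fraction = 0)
  expect_length(ch, 3)
  for (k in 1:3) {
    expect_equal(ch[[k]]$samples[2400], 5)
    expect_equal(ch[[k]]$peak_offset, 0L)
  }
})

test_that("jittered peak positions stay within 25% of the chunk width", {
  sr <- 48000
  wav <- rnorm(sr * 3, 0, 0.001)
  p_idx <- seq(20000, 120000, by = 500)
  rec <- make_recording(wav, sr, L1 = 0.01, L2 = 2.9, L3 = 2.92, L4 = 2.99)
  pk <- structure(list(times = (p_idx - 1) / sr, sample_rate = sr),
                  class = "peak_list")
  set.seed(8)
  ch <- slice_peak_centered(rec, pk)
  offs <- vapply(ch, `[[`, integer(1), "peak_offset")
  expect_true(all(offs >= -1200L & offs <= 1200L))
  # peak position inside the chunk: centre 2400 plus the offset
  pos <- 2400 + offs
  expect_true(all(pos >= 1200 & pos <= 3600))
})

test_that("chunks that would cross the recording boundary are discarded with a warning", {
  sr <- 48000
  wav <- rnorm(6000, 0, 0.001)
  pk <- structure(list(times = c(0.01, 0.12), sample_rate = sr),
                  class = "peak_list")
  rec <- make_recording(wav, sr, L1 = 0.001, L2 = 0.124, L3 = 0.124,
                        L4 = 0.1245)
  set.seed(1)
  expect_warning(ch <- slice_peak_centered(rec, pk), "discarded")
  expect_length(ch, 0)
})

test_that("mel spectrograms have the configured geometry", {
  set.seed(2)
  x <- rnorm(4800)
  ms <- mel_spectrogram(x, 48000)
  expect_equal(nrow(ms$values), 256)
  expect_equal(ncol(ms$values), 1 + 4800 %/% 512)  # 10 centred frames
  expect_true(all(is.finite(ms$values)))
  expect_true(all(ms$values <= 0 & ms$values >= -80))
  # deterministic: identical chunks yield bit-identical spectrograms
  expect_identical(ms$values, mel_spectrogram(x, 48000)$values)
})

test_that("an all-zero chunk maps to the dB floor and low rates are rejected", {
  ms <- mel_spectrogram(numeric(4800), 48000)
  expect_true(all(ms$values == -80))
  expect_error(mel_spectrogram(rnorm(100), 16000), "2\\*fmax")
})

test_that("the argmax mel bin is non-decreasing in tone frequency", {
  sr <- 48000
  t <- (0:4799) / sr
  bins <- vapply(c(500, 1000, 2000, 5000, 10000), function(f) {
    ms <- mel_spectrogram(sin(2 * pi * f * t), sr)
    which.max(rowMeans(ms$values))
  }, numeric(1))
  expect_true(all(diff(bins) > 0))
})
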