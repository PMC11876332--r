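test_that("grouped folds never split a recording and balance chunk counts", {
  set.seed(3)
  idx <- data.frame(
    chunk_id = 1:200,
    recording_id = rep(sprintf("r%02d", 1:20), times = rep(10, 20)))
  folds <- make_folds(idx, 5)
  expect_equal(folds$n_folds, 5L)
  # pairwise-disjoint recording sets, checked exhaustively
  sets <- lapply(1:5, function(f) {
    unique(idx$recording_id[folds$chunk_folds == f])
  })
  for (a in 1:4) for (b in (a + 1):5) {
    expect_length(intersect(sets[[a]], sets[[b]]), 0)
  }
  sizes <- as.numeric(table(folds$chunk_folds))
  expect_true(all(abs(sizes - mean(sizes)) / mean(sizes) <= 0.2))
})

test_that("five recordings give exactly one recording per fold", {
  set.seed(4)
  idx <- data.frame(chunk_id = 1:25, recording_id = rep(letters[1:5], 5))
  folds <- make_folds(idx, 5)
  expect_equal(sort(unname(folds$recording_folds)), 1:5)
  expect_error(make_folds(idx[idx$recording_id != "a", ], 5), "at least 5")
})

test_that("fold assignment is deterministic given the RNG state", {
  idx <- data.frame(chunk_id = 1:60, recording_id = rep(sprintf("r%d", 1:12), 5))
  set.seed(11)
  f1 <- make_folds(idx, 5)
  set.seed(11)
  f2 <- make_folds(idx, 5)
  expect_identical(f1$recording_folds, f2$recording_folds)
})

test_that("augmentation with degenerate ranges is the identity", {
  ch <- noise_chunks(1, 1, function(r) 30)[[1]]
  spec <- augmentation_spec(gain_db = c(0, 0), pitch_semitones = c(0, 0),
                           time_stretch = c(1, 1))
  set.seed(1)
  out <- augment(ch, spec)
  expect_identical(out$samples, ch$samples)
  expect_identical(out$label, ch$label)
})

test_that("a +5 dB gain scales amplitudes by 10^(5/20)", {
  ch <- noise_chunks(1, 1, function(r) 30)[[1]]
  spec <- augmentation_spec(gain_db = c(5, 5), pitch_semitones = c(0, 0),
                           time_stretch = c(1, 1))
  set.seed(1)
  out <- augment(ch, spec)
  expect_equal(out$samples, ch$samples * 10^(5 / 20), tolerance = 1e-12)
})

test_that("augmentation draws stay in range and preserve label and length", {
  ch <- noise_chunks(1, 1, function(r) 42)[[1]]
  spec <- augmentation_spec()
  set.seed(2)
  gains <- replicate(500, {
    g_only <- augmentation_spec(pitch_semitones = c(0, 0),
                                time_stretch = c(1, 1))
    out <- augment(ch, g_only)
    20 * log10(max(abs(out$samples)) / max(abs(ch$samples)))
  })
  expect_true(all(gains >= -5 - 1e-9 & gains <= 5 + 1e-9))
  set.seed(3)
  for (k in 1:20) {
    out <- augment(ch, spec)
    expect_length(out$samples, length(ch$samples))
    expect_identical(out$label, 42)
  }
})

test_that("the regression head is a single output for both architectures", {
  set.seed(1)
  small <- build_model("small", input_shape = c(64, 10))
  x <- array(0, c(64, 10, 1, 3))
  out <- predict_chunks(small, list())  # empty input contract
  expect_length(out, 0)
  fw <- asNamespace("vibrotemp")$nn_forward(small, x)
  expect_equal(dim(fw$out), c(1L, 3L))
  expect_true(all(is.finite(fw$out)))
})

test_that("the 18-layer residual network has the expected parameter count", {
  set.seed(1)
  net <- build_model("resnet18")
  # independent bookkeeping over the standard architecture table
  conv_p <- function(k, cin, cout) k * k * cin * cout
  bn_p <- function(c) 2 * c
  block <- function(cin, cout, down) {
    n <- conv_p(3, cin, cout) + bn_p(cout) + conv_p(3, cout, cout) + bn_p(cout)
    if (down) n <- n + conv_p(1, cin, cout) + bn_p(cout)
    n
  }
  expected <- conv_p(7, 3, 64) + bn_p(64) +
    block(64, 64, FALSE) + block(64, 64, FALSE) +
    block(64, 128, TRUE) + block(128, 128, FALSE) +
    block(128, 256, TRUE) + block(256, 256, FALSE) +
    block(256, 512, TRUE) + block(512, 512, FALSE) +
    (512 * 1 + 1)
  expect_equal(n_params(net), expected)
  # the classical 1000-class configuration has 11,689,512 parameters; the
  # 1-output head removes 512*1000+1000 and adds 512+1
  expect_equal(n_params(net), 11689512 - 513000 + 513)
})

test_that("the residual network forward pass returns a finite scalar per input", {
  set.seed(1)
  net <- build_model("resnet18")
  x0 <- prepare_resnet_input(matrix(-80, 256, 10))
  xb <- array(x0, c(224, 224, 3, 1))
  fw <- asNamespace("vibrotemp")$nn_forward(net, xb)
  expect_equal(dim(fw$out), c(1L, 1L))
  expect_true(is.finite(fw$out[1, 1]))
})

test_that("cosine annealing hits the documented endpoints and midpoint", {
  expect_equal(cosine_lr(0, 70), 0.001)
  expect_equal(cosine_lr(35, 70), 0.0001 + 0.0009 * 0.5)
  expect_equal(cosine_lr(70, 70), 0.0001)
})

test_that("training drives the loss to zero on a constant-label problem", {
  set.seed(5)
  chunks <- noise_chunks(8, 5, function(r) 30)
  folds <- make_folds(chunk_index(chunks), 5)
  cv <- train_model(chunks, folds,
                    train_config(epochs = 3, batch_size = 16, arch = "small",
                                 augment = FALSE, seed = 5))
  final <- cv$curves[cv$curves$epoch == 2, "test_mse"]
  expect_true(all(final < 1))
  expect_true(all(is.finite(cv$predictions$prediction)))
})

test_that("trained folds keep train and test recordings disjoint", {
  set.seed(6)
  chunks <- noise_chunks(6, 4, function(r) 20 + 5 * r)
  folds <- make_folds(chunk_index(chunks), 5)
  cv <- train_model(chunks, folds,
                    train_config(epochs = 1, batch_size = 8, arch = "small",
                                 augment = FALSE, seed = 6))
  for (f in 1:5) {
    te_rec <- unique(cv$predictions$recording_id[cv$predictions$fold == f])
    tr_rec <- unique(cv$predictions$recording_id[cv$predictions$fold != f])
    expect_length(intersect(te_rec, tr_rec), 0)
  }
  expect_false(cv$run_log$pretrained_loaded)
  expect_equal(cv$run_log$seed, 6)
})

test_that("recording aggregation averages in-motion chunks and marks empty sets", {
  expect_equal(aggregate_recording(c(30, 32, 34), c(1, 2, 3), c(0, 5)), 32)
  expect_true(is.na(aggregate_recording(numeric(0), numeric(0), c(0, 5))))
  # chunks before L1 (initiation pulse) are excluded from the aggregate
  preds <- c(99, 30, 32, 34)
  times <- c(0.3, 1.2, 1.5, 1.8)
  expect_equal(aggregate_recording(preds, times, c(1, 2)), 32)
  expect_true(is.na(aggregate_recording(c(99), c(0.3), c(1, 2))))
})
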