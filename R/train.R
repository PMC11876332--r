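#' Training configuration
#'
#' Defaults follow the study protocol for the full-scale run: 70 epochs,
#' batch size 32, an AdamW optimizer, mean-squared-error loss, and cosine
#' annealing of the learning rate from 0.001 down to 0.0001.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param lr_init,lr_final Initial / final learning rate
#'   (`lr_final <= lr_init`).
#' @param weight_decay Decoupled weight decay applied to conv/dense weights.
#' @param arch Model architecture, see [build_model()].
#' @param pretrained Passed to [build_model()].
#' @param augment Apply waveform augmentation to training chunks.
#' @param aug An [augmentation_spec()].
#' @param seed Training seed (fold models are seeded `seed + fold`).
#' @param verbose Print per-epoch progress.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 70L, batch_size = 32L, lr_init = 0.001,
                         lr_final = 0.0001, weight_decay = 0.01,
                         arch = "small", pretrained = FALSE,
                         augment = TRUE, aug = augmentation_spec(),
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_final <= lr_init, lr_init > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_final = lr_final,
                 weight_decay = weight_decay, arch = arch,
                 pretrained = pretrained, augment = augment, aug = aug,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_final + (lr_init - lr_final) * (1 + cos(pi * e / epochs)) / 2`,
#' so `lr(0) = lr_init` and `lr(epochs) = lr_final`.
#'
#' @param epoch Epoch index (0-based; may be fractional).
#' @param epochs Total number of epochs.
#' @param lr_init,lr_final Schedule endpoints.
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, epochs, lr_init = 0.001, lr_final = 0.0001) {
  lr_final + (lr_init - lr_final) * (1 + cos(pi * epoch / epochs)) / 2
}

#' Waveform augmentation ranges
#'
#' Uniform draw ranges for the three augmentations applied to training
#' chunks, in the order time-stretch, pitch-shift, gain. Pitch shift is
#' specified in semitones; time stretch as a duration factor.
#'
#' @param gain_db Gain range in dB.
#' @param pitch_semitones Pitch-shift range in semitones.
#' @param time_stretch Duration-factor range (1 = unchanged).
#' @return An `augmentation_spec` object.
#' @export
augmentation_spec <- function(gain_db = c(-5, 5), pitch_semitones = c(-3, 3),
                              time_stretch = c(0.9, 1.1)) {
  stopifnot(length(gain_db) == 2, length(pitch_semitones) == 2,
            length(time_stretch) == 2, all(time_stretch > 0))
  structure(list(gain_db = sort(gain_db),
                 pitch_semitones = sort(pitch_semitones),
                 time_stretch = sort(time_stretch)),
            class = "augmentation_spec")
}

fix_length <- function(x, n) {
  m <- length(x)
  if (m == n) return(x)
  if (m > n) {
    a <- (m - n) %/% 2L
    return(x[(a + 1L):(a + n)])
  }
  pre <- (n - m) %/% 2L
  c(numeric(pre), x, numeric(n - m - pre))
}

# Overlap-add granular time stretch; factor > 1 lengthens. Grains of
# `grain` samples at analysis hop grain/4 are re-spaced to hop*factor.
ola_stretch <- function(x, factor, grain = 1024L) {
  n <- length(x)
  grain <- min(grain, n)
  ha <- max(1L, grain %/% 4L)
  hs <- max(1L, round(ha * factor))
  n_gr <- max(1L, (n - grain) %/% ha + 1L)
  out_len <- (n_gr - 1L) * hs + grain
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(grain) - 1) / grain)
  y <- numeric(out_len)
  wsum <- numeric(out_len)
  for (k in seq_len(n_gr)) {
    seg <- x[((k - 1L) * ha + 1L):((k - 1L) * ha + grain)]
    pos <- (k - 1L) * hs
    y[(pos + 1L):(pos + grain)] <- y[(pos + 1L):(pos + grain)] + seg * w
    wsum[(pos + 1L):(pos + grain)] <- wsum[(pos + 1L):(pos + grain)] + w
  }
  y / pmax(wsum, 1e-8)
}

pitch_shift <- function(x, semitones) {
  r <- 2^(semitones / 12)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), by = r))$y
}

#' Augment a waveform chunk
#'
#' Draws one value from each range of `spec` (current RNG state) and applies
#' time stretch, then pitch shift, then gain; the result is re-cropped or
#' zero-padded back to the chunk's fixed length. Label, length and metadata
#' are unchanged. Degenerate ranges at the identity values (factor 1, 0
#' semitones, 0 dB) return the chunk unmodified.
#'
#' @param chunk A `chunk` object.
#' @param spec An [augmentation_spec()].
#' @return The augmented `chunk`.
#' @export
augment <- function(chunk, spec = augmentation_spec()) {
  n <- length(chunk$samples)
  s <- stats::runif(1, spec$time_stretch[1], spec$time_stretch[2])
  p <- stats::runif(1, spec$pitch_semitones[1], spec$pitch_semitones[2])
  g <- stats::runif(1, spec$gain_db[1], spec$gain_db[2])
  x <- chunk$samples
  if (s != 1) x <- fix_length(ola_stretch(x, s), n)
  if (p != 0) x <- fix_length(pitch_shift(x, p), n)
  if (g != 0) x <- x * 10^(g / 20)
  chunk$samples <- x
  chunk
}

#' Recording-grouped fold assignment
#'
#' Assigns whole recordings to folds so no recording's chunks are split
#' across folds (zero leakage), while balancing per-fold chunk counts:
#' recordings are shuffled, ordered by chunk count (largest first), and
#' each is placed into the currently smallest fold. Deterministic given the
#' RNG state.
#'
#' @param index Chunk index data.frame (see [chunk_index()]) with at least
#'   `chunk_id` and `recording_id`.
#' @param n_folds Number of folds (default 5).
#' @return A `fold_split`: `n_folds`, `recording_folds` (named integer
#'   vector), and `chunk_folds` aligned with the rows of `index`.
#' @export
make_folds <- function(index, n_folds = 5L) {
  recs <- unique(index$recording_id)
  if (length(recs) < n_folds) {
    stop("need at least ", n_folds, " recordings for ", n_folds,
         "-fold grouped cross-validation; got ", length(recs))
  }
  cnt <- table(index$recording_id)[recs]
  shuffled <- sample(recs)
  ord <- shuffled[order(-as.numeric(cnt[shuffled]))]
  fold_of <- stats::setNames(integer(length(ord)), ord)
  totals <- numeric(n_folds)
  for (r in ord) {
    f <- which.min(totals)
    fold_of[r] <- f
    totals[f] <- totals[f] + as.numeric(cnt[r])
  }
  structure(list(n_folds = as.integer(n_folds),
                 recording_folds = fold_of,
                 chunk_folds = unname(fold_of[index$recording_id])),
            class = "fold_split")
}

mel_input <- function(values, floor_db = -80) (values - floor_db) / (-floor_db)

chunks_to_input <- function(mels, floor_db = -80) {
  H <- nrow(mels[[1]]); W <- ncol(mels[[1]])
  x <- array(0, c(H, W, 1L, length(mels)))
  for (i in seq_along(mels)) x[, , 1L, i] <- mel_input(mels[[i]], floor_db)
  x
}

net_predict_std <- function(net, x, batch = 64L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (a in seq(1L, n, by = batch)) {
    b <- min(a + batch - 1L, n)
    fw <- nn_forward(net, x[, , , a:b, drop = FALSE], training = FALSE)
    out[a:b] <- as.numeric(fw$out)
  }
  out
}

#' Train the temperature regressor under grouped cross-validation
#'
#' For each fold, trains on the other folds' chunks (optionally augmented
#' each epoch) and evaluates on the held-out fold after every epoch.
#' Labels are z-scored on the training folds internally so the MSE the
#' optimizer sees is O(1); all reported losses and predictions are on the
#' degrees-Celsius scale. The "best" RMSE of a fold is its minimum held-out
#' RMSE over epochs.
#'
#' @param chunks List of `chunk` objects (waveform snippets with labels).
#' @param folds A [make_folds()] split aligned with `chunks`.
#' @param cfg A [train_config()].
#' @param group_lookup Optional named vector mapping `recording_id` to its
#'   temperature group, copied into the prediction table.
#' @return A `cv_result`: per-fold `models`, a `curves` data.frame
#'   (fold, epoch, lr, train_mse, test_mse), `best_rmse` per fold with
#'   mean/sd, held-out `predictions` (chunk_id, recording_id, group, truth,
#'   prediction, fold) from each fold's final model, and a `run_log`.
#' @export
train_model <- function(chunks, folds, cfg = train_config(),
                        group_lookup = NULL) {
  stopifnot(length(chunks) == length(folds$chunk_folds))
  y <- vapply(chunks, `[[`, numeric(1), "label")
  rec_ids <- vapply(chunks, `[[`, character(1), "recording_id")
  sr <- chunks[[1]]$sample_rate

  mels <- lapply(chunks, function(ch) mel_spectrogram(ch)$values)
  in_shape <- dim(mels[[1]])

  curves <- list()
  models <- vector("list", folds$n_folds)
  best_rmse <- numeric(folds$n_folds)
  preds_all <- rep(NA_real_, length(chunks))
  pretrained_loaded <- FALSE

  for (f in seq_len(folds$n_folds)) {
    te <- which(folds$chunk_folds == f)
    tr <- which(folds$chunk_folds != f)
    if (length(tr) == 0) stop("empty training fold")
    if (length(te) == 0) stop("empty test fold ", f)

    mu_y <- mean(y[tr])
    sd_y <- stats::sd(y[tr])
    if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1

    set.seed(cfg$seed + f)
    net <- build_model(cfg$arch, input_shape = in_shape,
                       pretrained = cfg$pretrained)
    pretrained_loaded <- pretrained_loaded || isTRUE(net$pretrained_loaded)
    net$label_mean <- mu_y
    net$label_sd <- sd_y
    state <- adamw_init(net)

    x_te <- chunks_to_input(mels[te])
    y_tr_std <- (y[tr] - mu_y) / sd_y

    fold_curve <- data.frame(fold = integer(0))
    test_mse_hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs) - 1L) {
      lr <- cosine_lr(ep, cfg$epochs, cfg$lr_init, cfg$lr_final)
      perm <- sample(length(tr))
      ep_loss <- 0
      n_b <- 0L
      for (a in seq(1L, length(tr), by = cfg$batch_size)) {
        b <- min(a + cfg$batch_size - 1L, length(tr))
        sel <- perm[a:b]
        if (cfg$augment) {
          bm <- lapply(tr[sel], function(i) {
            mel_spectrogram(augment(chunks[[i]], cfg$aug))$values
          })
        } else {
          bm <- mels[tr[sel]]
        }
        xb <- chunks_to_input(bm)
        yb <- y_tr_std[sel]
        fw <- nn_forward(net, xb, training = TRUE)
        net <- fw$net
        resid <- as.numeric(fw$out) - yb
        ep_loss <- ep_loss + mean(resid^2)
        n_b <- n_b + 1L
        dout <- matrix(2 * resid / length(resid), 1L)
        bk <- nn_backward(net, fw$caches, dout)
        upd <- adamw_update(net, bk$grads, state, lr,
                            weight_decay = cfg$weight_decay)
        net <- upd$net
        state <- upd$state
      }
      p_te <- net_predict_std(net, x_te) * sd_y + mu_y
      test_mse <- mean((p_te - y[te])^2)
      test_mse_hist[ep + 1L] <- test_mse
      fold_curve <- rbind(fold_curve, data.frame(
        fold = f, epoch = ep, lr = lr,
        train_mse = ep_loss / n_b * sd_y^2, test_mse = test_mse))
      if (cfg$verbose) {
        message(sprintf("fold %d epoch %02d lr %.2e train %.2f test %.2f",
                        f, ep, lr, ep_loss / n_b * sd_y^2, test_mse))
      }
    }
    best_rmse[f] <- sqrt(min(test_mse_hist))
    preds_all[te] <- net_predict_std(net, x_te) * sd_y + mu_y
    models[[f]] <- net
    curves[[f]] <- fold_curve
  }

  predictions <- data.frame(
    chunk_id = seq_along(chunks), recording_id = rec_ids,
    group = if (is.null(group_lookup)) NA_real_ else
      unname(group_lookup[rec_ids]),
    truth = y, prediction = preds_all, fold = folds$chunk_folds,
    stringsAsFactors = FALSE)

  structure(list(
    models = models, curves = do.call(rbind, curves),
    best_rmse = best_rmse,
    best_rmse_mean = mean(best_rmse), best_rmse_sd = stats::sd(best_rmse),
    predictions = predictions,
    run_log = list(seed = cfg$seed, config = unclass(cfg),
                   pretrained_loaded = pretrained_loaded,
                   sample_rate = sr, n_chunks = length(chunks),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds | best held-out RMSE per fold: %s\n  mean %.3f +/- %.3f C\n",
    length(x$models), paste(sprintf("%.2f", x$best_rmse), collapse = ", "),
    x$best_rmse_mean, x$best_rmse_sd))
  invisible(x)
}

#' Predict temperatures for waveform chunks
#'
#' @param net A trained `vt_net` (carries its label standardization).
#' @param chunks List of `chunk` objects.
#' @return Numeric vector of predicted temperatures in degrees C.
#' @export
predict_chunks <- function(net, chunks) {
  if (length(chunks) == 0) return(numeric(0))
  mels <- lapply(chunks, function(ch) mel_spectrogram(ch)$values)
  x <- chunks_to_input(mels)
  net_predict_std(net, x) * net$label_sd + net$label_mean
}

#' Aggregate chunk predictions to a recording-level temperature
#'
#' The recording-level prediction is the mean over its forward-motion
#' chunks (those whose centre lies inside `window`, by default `[L1, L2]`);
#' initiation-pulse or retraction chunks are excluded. A recording with no
#' in-window chunks yields `NA` (an undefined-prediction marker, not a
#' number).
#'
#' @param predictions Numeric per-chunk predictions, degrees C.
#' @param center_times Chunk centre times in seconds, aligned with
#'   `predictions`.
#' @param window Two-element window `c(L1, L2)` in seconds.
#' @return Mean prediction, or `NA_real_` when no chunk qualifies.
#' @export
aggregate_recording <- function(predictions, center_times, window) {
  stopifnot(length(predictions) == length(center_times), length(window) == 2)
  keep <- center_times >= window[1] & center_times <= window[2]
  if (!any(keep)) return(NA_real_)
  mean(predictions[keep])
}
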