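#' Build a convolutional temperature regressor
#'
#' Two architectures share the same single-output regression head:
#'
#' * `"resnet18"`: the standard 18-layer residual network (7x7/2 stem with
#'   batch norm and 3x3/2 max pooling, four stages of two basic blocks at
#'   64/128/256/512 channels, global average pooling) with the final fully
#'   connected layer reduced from 1000 classes to a single regression
#'   output. Spectrogram inputs are adapted via
#'   [prepare_resnet_input()] (channel replication + bilinear resize to
#'   224x224).
#' * `"small"`: a compact 3-conv-block network operating directly on the
#'   `n_mels x n_frames` spectrogram, for fast CPU experiments and tests.
#'
#' Pretrained backbone weights are looked up at
#' `getOption("vibrotemp.resnet18_weights")` (an RDS file of layer
#' parameters). When unavailable -- the normal offline case -- the network
#' initializes randomly and the fact is recorded in the returned object
#' (`pretrained_loaded`), which training copies into its run log.
#'
#' @param arch `"small"` or `"resnet18"`.
#' @param input_shape `c(H, W)` spatial input size. Defaults: `c(256, 10)`
#'   (a 100 ms mel spectrogram) for `"small"`, `c(224, 224)` for
#'   `"resnet18"`.
#' @param pretrained Attempt to load pretrained backbone weights.
#' @return A `vt_net` with a 1-output head.
#' @export
build_model <- function(arch = c("small", "resnet18"), input_shape = NULL,
                        pretrained = FALSE) {
  arch <- match.arg(arch)
  if (arch == "small") {
    if (is.null(input_shape)) input_shape <- c(256L, 10L)
    net <- build_small_cnn(input_shape)
  } else {
    if (is.null(input_shape)) input_shape <- c(224L, 224L)
    net <- build_resnet18(input_shape)
  }
  net$pretrained_loaded <- FALSE
  if (pretrained) {
    wpath <- getOption("vibrotemp.resnet18_weights", "")
    if (arch == "resnet18" && nzchar(wpath) && file.exists(wpath)) {
      net <- load_net_weights(net, wpath)
      net$pretrained_loaded <- TRUE
    } else {
      message("pretrained weights unavailable; using random initialization")
    }
  }
  net
}

conv_out_dim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# zero-initialized regression head: the model starts at the (standardized)
# label mean and the head learns before the features, a standard stabilizer
# for regression fine-tuning
zero_head <- function(layer) {
  layer$W[] <- 0
  layer$b[] <- 0
  layer
}

build_small_cnn <- function(input_shape) {
  H <- input_shape[1]; W <- input_shape[2]
  h1 <- conv_out_dim(H, 3L, 2L, 1L); w1 <- conv_out_dim(W, 3L, 1L, 1L)
  h2 <- conv_out_dim(h1, 3L, 2L, 1L); w2 <- conv_out_dim(w1, 3L, 1L, 1L)
  h3 <- conv_out_dim(h2, 3L, 2L, 1L); w3 <- conv_out_dim(w2, 3L, 2L, 1L)
  flat <- h3 * w3 * 32L
  layers <- list(
    nn_conv(3L, 3L, 1L, 8L, stride = c(2L, 1L), bias = FALSE),
    nn_bn(8L), nn_relu(),
    nn_conv(3L, 3L, 8L, 16L, stride = c(2L, 1L), bias = FALSE),
    nn_bn(16L), nn_relu(),
    nn_conv(3L, 3L, 16L, 32L, stride = c(2L, 2L), bias = FALSE),
    nn_bn(32L), nn_relu(),
    nn_flatten(),
    nn_dense(flat, 32L), nn_relu(),
    zero_head(nn_dense(32L, 1L)))
  structure(list(layers = layers, arch = "small",
                 input_shape = c(input_shape, 1L),
                 label_mean = 0, label_sd = 1),
            class = "vt_net")
}

build_resnet18 <- function(input_shape) {
  layers <- list(
    nn_conv(7L, 7L, 3L, 64L, stride = c(2L, 2L), pad = c(3L, 3L),
            bias = FALSE),
    nn_bn(64L), nn_relu(), nn_maxpool(3L, 2L, 1L),
    nn_resblock(64L, 64L), nn_resblock(64L, 64L),
    nn_resblock(64L, 128L, stride = 2L), nn_resblock(128L, 128L),
    nn_resblock(128L, 256L, stride = 2L), nn_resblock(256L, 256L),
    nn_resblock(256L, 512L, stride = 2L), nn_resblock(512L, 512L),
    nn_gap(),
    nn_dense(512L, 1L))
  structure(list(layers = layers, arch = "resnet18",
                 input_shape = c(input_shape, 3L),
                 label_mean = 0, label_sd = 1),
            class = "vt_net")
}

load_net_weights <- function(net, path) {
  w <- readRDS(path)
  for (l in seq_along(w)) {
    for (f in names(w[[l]])) net$layers[[l]][[f]] <- w[[l]][[f]]
  }
  net
}

#' @export
print.vt_net <- function(x, ...) {
  cat(sprintf("<vt_net %s> input %s | %s parameters | head: 1 output\n",
              x$arch, paste(x$input_shape, collapse = "x"),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Bilinear image resize
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Target size.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  yi <- if (out_h == 1) rep(1, 1) else seq(1, H, length.out = out_h)
  xi <- if (out_w == 1) rep(1, 1) else seq(1, W, length.out = out_w)
  y0 <- pmin(floor(yi), H - 1L); y1 <- y0 + 1L; fy <- yi - y0
  x0 <- pmin(floor(xi), W - 1L); x1 <- x0 + 1L; fx <- xi - x0
  if (H == 1) { y0 <- y1 <- rep(1L, out_h); fy <- rep(0, out_h) }
  if (W == 1) { x0 <- x1 <- rep(1L, out_w); fx <- rep(0, out_w) }
  a <- m[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx)) +
    m[y1, x0, drop = FALSE] * (fy %o% (1 - fx)) +
    m[y0, x1, drop = FALSE] * ((1 - fy) %o% fx) +
    m[y1, x1, drop = FALSE] * (fy %o% fx)
  a
}

#' Adapt a mel spectrogram to the residual backbone's input
#'
#' Replicates the single spectrogram channel to 3 channels and resizes to
#' the backbone's native 224x224 resolution by bilinear interpolation.
#'
#' @param values `n_mels x n_frames` matrix (dB).
#' @param size Target spatial size (default 224).
#' @return Array `(size, size, 3)`.
#' @export
prepare_resnet_input <- function(values, size = 224L) {
  r <- resize_bilinear(values, size, size)
  array(rep(r, 3L), c(size, size, 3L))
}
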