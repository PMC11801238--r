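#' @title Spectrum-to-spectrum enhancement network
#' @description
#' A configurable network mapping the pair of packed time-domain planes to
#' the enhanced frequency-domain spectrum plus a confidence plane. The
#' architecture processes both time axes with dilated one-dimensional
#' convolution blocks, passes every feature channel through a fixed linear
#' time-to-frequency transform, refines in the frequency domain with 2D
#' convolution blocks, and ends in a 1x1 head producing two channels
#' (intensity and confidence). At the default zero-fill sizes the input
#' tensor is (2, 400, 512) and the output (512, 400, 2). All gradients are
#' hand-derived; training uses ADAM.
#' @name network
NULL

#' Pack a hypercomplex plane into the real network layout
#'
#' Zero-fills a complex plane (`dim = c(n_h, n_c, 2)`) to the scheme's
#' zero-fill targets and packs it into a real matrix of size
#' `(2*zf_h, 2*zf_c)`: rows are (Re, Im) halves of the 1H axis, columns
#' (Re, Im) halves of the 13C axis.
#'
#' @param plane Complex array from [synthesize_fid()].
#' @param zf_h,zf_c Zero-fill targets in complex points.
#' @return Real matrix `(2*zf_h) x (2*zf_c)`.
#' @export
pack_plane <- function(plane, zf_h, zf_c) {
  d <- dim(plane)
  n_h <- d[1]; n_c <- d[2]
  if (n_h > zf_h || n_c > zf_c) stop("plane larger than the zero-fill target")
  out <- matrix(0, 2 * zf_h, 2 * zf_c)
  ih <- seq_len(n_h); ic <- seq_len(n_c)
  out[ih, ic]               <- Re(plane[, , 1])
  out[zf_h + ih, ic]        <- Im(plane[, , 1])
  out[ih, zf_c + ic]        <- Re(plane[, , 2])
  out[zf_h + ih, zf_c + ic] <- Im(plane[, , 2])
  out
}

# inverse of pack_plane (recovers the leading n_h x n_c complex points)
unpack_plane <- function(packed, n_h, n_c, zf_h, zf_c) {
  ih <- seq_len(n_h); ic <- seq_len(n_c)
  out <- array(0 + 0i, dim = c(n_h, n_c, 2))
  out[, , 1] <- packed[ih, ic] + 1i * packed[zf_h + ih, ic]
  out[, , 2] <- packed[ih, zf_c + ic] + 1i * packed[zf_h + ih, zf_c + ic]
  out
}

#' Zero-fill and pack an input pair into the network input tensor
#'
#' The two acquired planes (coupling delay 0 and 2.3 ms) are zero-filled to
#' the scheme's targets and packed into a constant-size real tensor of shape
#' `(2, 2*zf_c, 2*zf_h)` — `(2, 400, 512)` at the default targets — with the
#' original samples in the leading positions and exact zeros appended.
#'
#' @param pair List of two complex planes (`input_nocoup`, `input_coup`).
#' @param acq The [acq_scheme()] of the pair.
#' @return Real array `(2, 2*zf_c, 2*zf_h)` of class `input_tensor`, with
#'   the scheme attached as attribute `acq`.
#' @export
zero_fill_input <- function(pair, acq) {
  stopifnot(inherits(acq, "acq_scheme"), length(pair) == 2L)
  x <- array(0, dim = c(2L, 2L * acq$zf_c, 2L * acq$zf_h))
  for (p in 1:2) {
    d <- dim(pair[[p]])
    if (d[1] != acq$n_h || d[2] != acq$n_c)
      stop("plane shape does not match the acquisition scheme")
    x[p, , ] <- t(pack_plane(pair[[p]], acq$zf_h, acq$zf_c))
  }
  structure(x, class = "input_tensor", acq = acq)
}

# input tensor -> internal (H, C, 2) layout
input_tensor_to_hc <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[3], d[2], 2L))
  out[, , 1] <- t(x[1, , ])
  out[, , 2] <- t(x[2, , ])
  out
}

#' Network configuration
#'
#' @param width Hidden channel count (filter count of every hidden layer);
#'   scales the parameter count.
#' @param depth_time Number of dilated convolution blocks on the time-domain
#'   tensor (axes alternate 13C, 1H; dilation doubles per block).
#' @param depth_freq Number of 3x3 convolution blocks in the
#'   frequency-domain refinement stage.
#' @param kernel_time Kernel length of the time-domain convolutions.
#' @param seed Integer seed for reproducible weight initialization.
#' @param zf_c,zf_h Zero-fill targets (complex points) fixing the tensor
#'   sizes; the defaults give the (2, 400, 512) -> (512, 400, 2) contract.
#' @param beta1,beta2,eps ADAM hyperparameters.
#' @param batch_size Training sets per mini-batch.
#' @param checkpoint_interval Batches between checkpoints.
#' @param apod_offset Sine-bell offset (radians) of the loss-domain
#'   convolution applied to predicted, target and sigma planes.
#' @return List of class `network_config`.
#' @export
network_config <- function(width = 12, depth_time = 3, depth_freq = 3,
                           kernel_time = 5, seed = 1L,
                           zf_c = 200, zf_h = 256,
                           beta1 = 0.9, beta2 = 0.98, eps = 1e-9,
                           batch_size = 4, checkpoint_interval = 2000,
                           apod_offset = 0.4 * pi) {
  stopifnot(width >= 1, depth_time >= 1, depth_freq >= 0,
            kernel_time %% 2 == 1, zf_c >= 2, zf_h >= 2, batch_size >= 1)
  structure(as.list(environment()), class = "network_config")
}

# ---- layer primitives -------------------------------------------------------

# shift an (H, C, ch) array by (oh, oc), zero-filling vacated positions
shift_hc <- function(x, oh, oc) {
  if (oh == 0 && oc == 0) return(x)
  d <- dim(x)
  y <- array(0, d)
  hs <- seq_len(d[1]) + oh; hok <- hs >= 1 & hs <= d[1]
  cs <- seq_len(d[2]) + oc; cok <- cs >= 1 & cs <= d[2]
  y[which(hok), which(cok), ] <- x[hs[hok], cs[cok], , drop = FALSE]
  y
}

as_mat <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
as_arr <- function(x, H, C) { dim(x) <- c(H, C, ncol(x)); x }

# generic tap convolution: W has dim (n_taps, cin, cout), taps is a matrix
# of (oh, oc) offsets
conv_forward <- function(x, W, b, taps) {
  d <- dim(x); H <- d[1]; C <- d[2]
  cout <- dim(W)[3]
  y <- matrix(rep(b, each = H * C), H * C, cout)
  for (k in seq_len(nrow(taps))) {
    y <- y + as_mat(shift_hc(x, taps[k, 1], taps[k, 2])) %*%
      matrix(W[k, , ], dim(W)[2], dim(W)[3])
  }
  as_arr(y, H, C)
}

conv_backward <- function(gy, x, W, taps) {
  d <- dim(x); H <- d[1]; C <- d[2]
  gym <- as_mat(gy)
  gW <- array(0, dim(W)); gx <- array(0, d)
  for (k in seq_len(nrow(taps))) {
    xs <- as_mat(shift_hc(x, taps[k, 1], taps[k, 2]))
    gW[k, , ] <- crossprod(xs, gym)
    gxk <- as_arr(tcrossprod(gym, matrix(W[k, , ], dim(W)[2], dim(W)[3])), H, C)
    gx <- gx + shift_hc(gxk, -taps[k, 1], -taps[k, 2])
  }
  list(gx = gx, gW = gW, gb = colSums(gym))
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

taps_axis <- function(axis, kernel, dilation) {
  off <- (seq_len(kernel) - (kernel + 1) / 2) * dilation
  if (axis == "c") cbind(0, off) else cbind(off, 0)
}
taps_2d <- function() as.matrix(expand.grid(oh = -1:1, oc = -1:1))

# ---- model ------------------------------------------------------------------

#' Build an enhancement model
#'
#' Creates the layer stack and initializes weights reproducibly from
#' `config$seed`. Fixed (non-trainable) components — the packed-time to
#' real-frequency transforms and the loss-domain sine-bell convolution
#' operators — are precomputed and stored on the model.
#'
#' @param config A [network_config()].
#' @return Object of class `enhancer_model`.
#' @export
build_model <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(config$seed))

  w <- config$width
  layers <- list()
  cin <- 2L
  for (b in seq_len(config$depth_time)) {
    axis <- if (b %% 2 == 1) "c" else "h"
    taps <- taps_axis(axis, config$kernel_time, 2^((b - 1) %/% 2))
    layers[[length(layers) + 1L]] <- list(
      type = "conv", taps = taps,
      W = array(stats::rnorm(nrow(taps) * cin * w, 0,
                             sqrt(2 / (nrow(taps) * cin))),
                dim = c(nrow(taps), cin, w)),
      b = rep(0, w),
      residual = (cin == w), activation = TRUE)
    cin <- w
  }
  layers[[length(layers) + 1L]] <- list(type = "transform")
  for (b in seq_len(config$depth_freq)) {
    taps <- taps_2d()
    layers[[length(layers) + 1L]] <- list(
      type = "conv", taps = taps,
      W = array(stats::rnorm(9 * cin * w, 0, sqrt(2 / (9 * cin))),
                dim = c(9L, cin, w)),
      b = rep(0, w),
      residual = (cin == w), activation = TRUE)
    cin <- w
  }
  layers[[length(layers) + 1L]] <- list(
    type = "conv", taps = cbind(0, 0),
    W = array(stats::rnorm(cin * 2, 0, 0.05 * sqrt(1 / cin)),
              dim = c(1L, cin, 2L)),
    b = rep(0, 2),
    residual = FALSE, activation = FALSE)

  structure(list(
    config = config,
    layers = layers,
    Mh = freq_matrix(config$zf_h),
    Mc = freq_matrix(config$zf_c),
    Ah = apod_matrix(2L * config$zf_h, config$apod_offset),
    Ac = apod_matrix(2L * config$zf_c, config$apod_offset)
  ), class = "enhancer_model")
}

#' @export
print.enhancer_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    if (l$type == "conv") length(l$W) + length(l$b) else 0L, numeric(1)))
  cat(sprintf("enhancement network: %d layers, %d parameters, grids (2, %d, %d) -> (%d, %d, 2)\n",
              length(x$layers), np, 2 * x$config$zf_c, 2 * x$config$zf_h,
              2 * x$config$zf_h, 2 * x$config$zf_c))
  invisible(x)
}

# forward pass on the internal (H, C, 2) layout; returns output (H, C, 2)
# and, if requested, per-layer caches for backprop
forward_net <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "transform") {
      d <- dim(x)
      y <- array(0, d)
      for (ch in seq_len(d[3])) y[, , ch] <- model$Mh %*% x[, , ch] %*% t(model$Mc)
      if (keep_cache) caches[[li]] <- list()
      x <- y
    } else {
      z <- conv_forward(x, l$W, l$b, l$taps)
      a <- if (l$activation) elu(z) else z
      y <- if (l$residual) x + a else a
      if (keep_cache) caches[[li]] <- list(x = x, z = z)
      x <- y
    }
  }
  list(out = x, caches = caches)
}

# backward pass; returns gradients as a list parallel to model$layers
backward_net <- function(model, caches, gout) {
  grads <- vector("list", length(model$layers))
  g <- gout
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    if (l$type == "transform") {
      d <- dim(g)
      gx <- array(0, d)
      for (ch in seq_len(d[3])) gx[, , ch] <- t(model$Mh) %*% g[, , ch] %*% model$Mc
      grads[[li]] <- list()
      g <- gx
    } else {
      cc <- caches[[li]]
      ga <- g
      gz <- if (l$activation) ga * elu_grad(cc$z) else ga
      bk <- conv_backward(gz, cc$x, l$W, l$taps)
      gx <- bk$gx
      if (l$residual) gx <- gx + g
      grads[[li]] <- list(gW = bk$gW, gb = bk$gb)
      g <- gx
    }
  }
  grads
}

#' Run inference on a pair of time-domain planes
#'
#' Zero-fills and packs the pair, runs the network, and returns the enhanced
#' intensity plane together with the confidence plane and the derived sigma
#' plane. With `apodize = TRUE` (the default) the intensity and sigma planes
#' are convolved with the same sine-bell operator used when computing the
#' losses, so inference output and training target share conventions.
#' Inference is deterministic.
#'
#' @param model A trained (or freshly built) [build_model()] model.
#' @param pair List of the two complex time-domain planes.
#' @param acq The pair's [acq_scheme()]; its zero-fill targets must match
#'   the model configuration.
#' @param apodize Apply the loss-convention sine-bell convolution.
#' @param scale Optional intensity normalization factor; by default the
#'   input is scaled so its frequency-domain maximum absolute value is 1
#'   (the convention used in training), and the output intensity is
#'   returned on the original scale.
#' @return Object of class `predicted_spectrum`: real matrices `intensity`,
#'   `confidence` (raw scores), `sigma` (both `(2*zf_h) x (2*zf_c)`), plus
#'   frequency axes `axis_h`, `axis_c` in Hz.
#' @export
infer <- function(model, pair, acq, apodize = TRUE, scale = NULL) {
  stopifnot(inherits(model, "enhancer_model"))
  if (acq$zf_c != model$config$zf_c || acq$zf_h != model$config$zf_h)
    stop("acquisition zero-fill targets do not match the model configuration")
  xt <- zero_fill_input(pair, acq)
  x <- input_tensor_to_hc(xt)
  if (is.null(scale)) {
    f0 <- model$Mh %*% x[, , 1] %*% t(model$Mc)
    scale <- 1 / max(abs(f0))
    if (!is.finite(scale)) scale <- 1
  }
  fw <- forward_net(model, x * scale, keep_cache = FALSE)
  intensity <- fw$out[, , 1]
  conf <- fw$out[, , 2]
  sigma <- sigma_from_confidence(conf)
  if (apodize) {
    intensity <- apply_sep(intensity, model$Ah, model$Ac)
    sigma <- pmax(apply_sep(sigma, model$Ah, model$Ac), 1e-8)
  }
  structure(list(intensity = intensity / scale,
                 confidence = conf,
                 sigma = sigma / scale,
                 axis_h = freq_axis(2L * acq$zf_h, acq$sw_h),
                 axis_c = freq_axis(2L * acq$zf_c, acq$sw_c),
                 scale = scale),
            class = "predicted_spectrum")
}

#' @export
print.predicted_spectrum <- function(x, ...) {
  cat(sprintf("predicted spectrum: %d x %d (1H x 13C), max intensity %.3g, median sigma %.3g\n",
              nrow(x$intensity), ncol(x$intensity),
              max(x$intensity), stats::median(x$sigma)))
  invisible(x)
}
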