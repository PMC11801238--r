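# Fixed linear spectral transforms shared by processing and the network:
# sine-bell windows, packed-time -> real-frequency matrices, and the
# frequency-domain sine-bell convolution operator used by the loss.

.aromadec_cache <- new.env(parent = emptyenv())

#' Sine-bell window
#'
#' `w(u) = sin(offset + (pi - offset)*u)` on `u = 0 .. 1` over `n` points
#' (`u = (i-1)/(n-1)`). The default offset of `0.4*pi` gives
#' `w(0) = sin(0.4*pi) ~ 0.951` and `w(1) = 0`.
#'
#' @param n Number of points.
#' @param offset Window offset in radians.
#' @return Numeric vector of length `n`.
#' @export
sine_bell <- function(n, offset = 0.4 * pi) {
  stopifnot(n >= 1)
  u <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  sin(offset + (pi - offset) * u)
}

# full DFT matrix (forward, exp(-2 pi i j k / n)), complex n x n
dft_matrix <- function(n) {
  jk <- outer(0:(n - 1), 0:(n - 1))
  exp(-2i * pi * jk / n)
}

# Packed-time -> real-frequency matrix for one axis.
# Input: packed vector [Re z (n); Im z (n)] of n complex time points
# (already zero-filled to the grid). Output: 2n real spectrum points,
# Re(F(zero-fill(z) to 2n)), reordered to ascending frequency offset
# (-sw/2 .. +sw/2). Cached per n.
freq_matrix <- function(n) {
  key <- paste0("freqmat_", n)
  if (!is.null(.aromadec_cache[[key]])) return(.aromadec_cache[[key]])
  F2 <- dft_matrix(2L * n)[, seq_len(n), drop = FALSE]
  M <- cbind(Re(F2), -Im(F2))
  # fftshift rows: ascending frequency order
  M <- M[c((n + 1L):(2L * n), 1L:n), , drop = FALSE]
  .aromadec_cache[[key]] <- M
  M
}

# frequency axis (Hz offsets from carrier, ascending) for a 2n-point grid
freq_axis <- function(n2, sw) {
  ((-(n2 %/% 2)):(n2 %/% 2 - 1)) * sw / n2
}

# Real frequency-domain convolution operator equivalent to time-domain
# multiplication by a sine-bell: A = Re(F diag(w_sym) F^-1), with the window
# mirrored over negative lags so that real planes map to real planes.
# Cached per (n, offset).
apod_matrix <- function(n, offset = 0.4 * pi) {
  key <- sprintf("apodmat_%d_%.6f", n, offset)
  if (!is.null(.aromadec_cache[[key]])) return(.aromadec_cache[[key]])
  k <- 0:(n - 1)
  lag <- pmin(k, n - k)
  u <- pmin(lag / (n / 2), 1)
  w <- sin(offset + (pi - offset) * u)
  Fm <- dft_matrix(n)
  Finv <- Conj(Fm) / n
  A <- Re(Fm %*% (w * Finv))
  .aromadec_cache[[key]] <- A
  A
}

# apply the separable 2D operator: A_h %*% X %*% t(A_c)
apply_sep <- function(X, Ah, Ac) Ah %*% X %*% t(Ac)
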