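#' Acquisition scheme for a 2D aromatic 13C-1H experiment
#'
#' Bundles the spectral and digitization parameters of one 2D plane: sweep
#' widths, complex point counts, the homonuclear coupling evolution delay
#' `tau_coup`, and the zero-fill targets that fix the network's input grid.
#'
#' The direct dimension is 1H (t2), the indirect dimension is 13C (t1).
#' Arrays produced by the simulator are 1H-major: `dim = c(n_h, n_c, 2)`,
#' the third index holding the real/imaginary 13C (t1) quadrature components.
#'
#' @param sw_h 1H sweep width in Hz.
#' @param sw_c 13C sweep width in Hz.
#' @param n_c Number of complex points in the 13C dimension (at the default
#'   zero-fill grid, between 96 and 200).
#' @param n_h Number of complex points in the 1H dimension (at the default
#'   zero-fill grid, between 128 and 256).
#' @param tau_coup Coupling evolution delay in seconds (0 for the plain
#'   experiment, 2.3e-3 for the multiplet-encoding one).
#' @param zf_c,zf_h Zero-fill targets in complex points. The defaults
#'   (200, 256) give the fixed network input tensor (2, 400, 512).
#' @return An object of class `acq_scheme`.
#' @examples
#' acq <- acq_scheme(n_c = 128, n_h = 192, tau_coup = 2.3e-3)
#' @export
acq_scheme <- function(sw_h = 10000, sw_c = 5000, n_c = 200, n_h = 256,
                       tau_coup = 0, zf_c = 200, zf_h = 256) {
  stopifnot(is.numeric(sw_h), sw_h > 0, is.numeric(sw_c), sw_c > 0)
  if (!is.numeric(tau_coup) || length(tau_coup) != 1L || tau_coup < 0)
    stop("'tau_coup' must be a single non-negative number")
  n_c <- as.integer(n_c); n_h <- as.integer(n_h)
  zf_c <- as.integer(zf_c); zf_h <- as.integer(zf_h)
  if (n_c < 2L || n_h < 2L) stop("need at least 2 complex points per dimension")
  if (n_c > zf_c) stop("'n_c' exceeds the zero-fill target 'zf_c'")
  if (n_h > zf_h) stop("'n_h' exceeds the zero-fill target 'zf_h'")
  structure(list(sw_h = sw_h, sw_c = sw_c, n_c = n_c, n_h = n_h,
                 tau_coup = tau_coup, zf_c = zf_c, zf_h = zf_h),
            class = "acq_scheme")
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat(sprintf("2D acquisition: 1H %d cpts / %g Hz, 13C %d cpts / %g Hz, tau_coup %.4g ms, zero-fill (%d, %d)\n",
              x$n_h, x$sw_h, x$n_c, x$sw_c, 1000 * x$tau_coup, x$zf_h, x$zf_c))
  invisible(x)
}

# acquisition time grids (seconds)
acq_t1 <- function(acq) (seq_len(acq$n_c) - 1) / acq$sw_c
acq_t2 <- function(acq) (seq_len(acq$n_h) - 1) / acq$sw_h
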