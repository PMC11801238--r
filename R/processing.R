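#' @title Spectral processing
#' @description
#' Conventional processing of the hypercomplex time-domain planes:
#' sine-bell apodization, zero-filling, States-type Fourier transform of
#' both dimensions with optional phasing, and peak-intensity extraction
#' from the resulting real 2D spectrum.
#' @name processing
NULL

#' Process a time-domain plane to a real 2D spectrum
#'
#' Applies a sine-bell window and zero-fill in each dimension, Fourier
#' transforms the direct (1H) dimension, combines the two indirect
#' quadrature components (States), transforms the indirect (13C)
#' dimension, and returns the real 2D absorption spectrum with ascending
#' Hz-offset axes. With `window = NULL` (no apodization) the result equals
#' the fixed linear transform used inside the network, and (by Parseval)
#' the complex transform itself is energy-preserving up to the zero-fill
#' length factor.
#'
#' @param plane Complex time-domain array `dim = c(n_h, n_c, 2)`.
#' @param acq The plane's [acq_scheme()]; the output grid is
#'   `(2*zf_h) x (2*zf_c)`.
#' @param window Sine-bell offset in radians, or `NULL` for no window.
#' @param phase_h,phase_c Zero- and first-order phase corrections
#'   `c(p0, p1)` in radians applied after the corresponding transform.
#' @return List of class `nmr_spectrum`: `spec` (real matrix), `axis_h`,
#'   `axis_c` (Hz offsets, ascending).
#' @export
process_plane <- function(plane, acq, window = 0.4 * pi,
                          phase_h = c(0, 0), phase_c = c(0, 0)) {
  d <- dim(plane)
  if (is.null(d) || length(d) != 3L || !is.complex(plane))
    stop("expected a complex time-domain array (n_h, n_c, 2); ",
         "frequency-domain input is not accepted")
  stopifnot(inherits(acq, "acq_scheme"), d[1] == acq$n_h, d[2] == acq$n_c)
  n_h <- acq$n_h; n_c <- acq$n_c
  gh <- 2L * acq$zf_h; gc <- 2L * acq$zf_c

  if (!is.null(window)) {
    wh <- sine_bell(n_h, window)
    wc <- sine_bell(n_c, window)
    plane <- plane * array(wh, dim = d)
    plane <- aperm(aperm(plane, c(2, 1, 3)) * array(wc, dim = c(n_c, n_h, 2)),
                   c(2, 1, 3))
  }

  # direct (1H) dimension: zero-fill and FT both quadrature components
  ft_h <- function(m) {
    mm <- matrix(0 + 0i, gh, n_c)
    mm[seq_len(n_h), ] <- m
    s <- stats::mvfft(mm)
    if (any(phase_h != 0))
      s <- s * exp(1i * (phase_h[1] + phase_h[2] * (0:(gh - 1)) / gh))
    s
  }
  s1 <- ft_h(plane[, , 1])
  s2 <- ft_h(plane[, , 2])

  # States recombination: absorptive 1H parts become the complex t1 signal
  b <- t(Re(s1) + 1i * Re(s2))          # (n_c x gh)
  bb <- matrix(0 + 0i, gc, gh)
  bb[seq_len(n_c), ] <- b
  sc <- stats::mvfft(bb)
  if (any(phase_c != 0))
    sc <- sc * exp(1i * (phase_c[1] + phase_c[2] * (0:(gc - 1)) / gc))
  spec <- t(Re(sc))                     # (gh x gc)

  # reorder both axes to ascending frequency offsets
  spec <- spec[c((gh / 2 + 1):gh, 1:(gh / 2)), c((gc / 2 + 1):gc, 1:(gc / 2))]
  structure(list(spec = spec,
                 axis_h = freq_axis(gh, acq$sw_h),
                 axis_c = freq_axis(gc, acq$sw_c)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("processed spectrum: %d x %d points (1H x 13C), max %.4g\n",
              nrow(x$spec), ncol(x$spec), max(x$spec)))
  invisible(x)
}

#' Extract peak intensities from a spectrum
#'
#' For each requested position, returns the signed extremum (largest
#' absolute value) within a rectangular box around the position, plus the
#' local uncertainty: the value of `sigma` at the extremum when a sigma
#' plane is supplied, otherwise a robust noise level (median absolute
#' deviation of the whole plane).
#'
#' @param spec Real spectrum matrix, 1H along rows.
#' @param axis_h,axis_c Frequency axes in Hz (as from [process_plane()] or
#'   [infer()]).
#' @param positions Data frame (or 2-column matrix) of `h_hz`, `c_hz`
#'   positions.
#' @param box_h,box_c Box half-widths in Hz.
#' @param sigma Optional congruent uncertainty plane.
#' @return Data frame with `h_hz`, `c_hz` (requested), `h_found`, `c_found`
#'   (extremum location), `intensity`, `sigma`.
#' @export
extract_intensities <- function(spec, axis_h, axis_c, positions,
                                box_h = 50, box_c = 25, sigma = NULL) {
  positions <- as.data.frame(positions)
  names(positions)[1:2] <- c("h_hz", "c_hz")
  if (any(positions$h_hz < min(axis_h)) || any(positions$h_hz > max(axis_h)) ||
      any(positions$c_hz < min(axis_c)) || any(positions$c_hz > max(axis_c)))
    stop("a requested position lies outside the spectral bounds")
  noise <- stats::mad(as.numeric(spec))
  out <- positions
  out$h_found <- out$c_found <- out$intensity <- out$sigma <- NA_real_
  for (k in seq_len(nrow(positions))) {
    ih <- which(abs(axis_h - positions$h_hz[k]) <= box_h)
    ic <- which(abs(axis_c - positions$c_hz[k]) <= box_c)
    if (!length(ih)) ih <- which.min(abs(axis_h - positions$h_hz[k]))
    if (!length(ic)) ic <- which.min(abs(axis_c - positions$c_hz[k]))
    sub <- spec[ih, ic, drop = FALSE]
    imax <- arrayInd(which.max(abs(sub)), dim(sub))
    out$h_found[k] <- axis_h[ih[imax[1]]]
    out$c_found[k] <- axis_c[ic[imax[2]]]
    out$intensity[k] <- sub[imax]
    out$sigma[k] <- if (!is.null(sigma)) sigma[ih[imax[1]], ic[imax[2]]] else noise
  }
  out
}

#' Convert Hz offsets to ppm
#'
#' @param hz Offset(s) in Hz from the carrier.
#' @param obs Observe frequency in MHz.
#' @param carrier_ppm Carrier position in ppm.
#' @return Chemical shift(s) in ppm.
#' @export
hz_to_ppm <- function(hz, obs, carrier_ppm = 0) carrier_ppm + hz / obs

#' @rdname hz_to_ppm
#' @param ppm Chemical shift(s) in ppm.
#' @export
ppm_to_hz <- function(ppm, obs, carrier_ppm = 0) (ppm - carrier_ppm) * obs
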