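#' @title Synthetic aromatic 13C-1H spectrum simulator
#' @description
#' Generates the training triples used to learn virtual 13C decoupling:
#' two complementary input planes (coupling evolution delay `tau_coup` of 0
#' and 2.3 ms) and a high-resolution target plane that is free of splittings
#' in the 13C dimension and has its 13C transverse relaxation rate halved.
#' @name simulator
NULL

#' Sample one-bond 13C-13C coupling pairs
#'
#' Each cross-peak carries two active carbon couplings, each drawn from a
#' normal distribution (mean 63 Hz, SD 10 Hz) and then independently set to
#' zero with probability `p_zero` (default 20%). The zero pattern fixes the
#' multiplet class: both zero gives a singlet (4%), exactly one zero a
#' doublet (32%), none zero a triplet (64%).
#'
#' @param n Number of coupling pairs to draw.
#' @param mean,sd Normal distribution of the coupling magnitude in Hz.
#' @param p_zero Probability that each coupling is independently zeroed.
#' @return A list with numeric vectors `j1` and `j2` (Hz).
#' @examples
#' set.seed(1)
#' j <- sample_carbon_couplings(5)
#' @export
sample_carbon_couplings <- function(n, mean = 63, sd = 10, p_zero = 0.2) {
  if (!is.numeric(p_zero) || p_zero < 0 || p_zero > 1)
    stop("'p_zero' must be a probability in [0, 1]")
  if (!is.numeric(sd) || sd < 0) stop("'sd' must be non-negative")
  j1 <- stats::rnorm(n, mean, sd)
  j2 <- stats::rnorm(n, mean, sd)
  j1[stats::runif(n) < p_zero] <- 0
  j2[stats::runif(n) < p_zero] <- 0
  list(j1 = j1, j2 = j2)
}

#' Place 1H chemical shifts away from the spectrum edge
#'
#' Initial 1H offsets are squashed through a pair of tanh terms,
#' `0.2*sw*tanh(6*d0/sw) + 0.3*sw*tanh(2*d0/sw)`, which concentrates
#' cross-peaks near the carrier (increasing overlap, as in crowded aromatic
#' regions) while guaranteeing `|delta_h| < 0.5*sw` so no peak sits on the
#' 1H edge of the spectrum.
#'
#' @param delta_h0 Initial 1H offset(s) in Hz (typically normal with SD sw/4).
#' @param sw_h 1H sweep width in Hz.
#' @return Placed offsets in Hz, strictly inside (-sw_h/2, sw_h/2).
#' @examples
#' place_proton_shift(2000, 8000)
#' @export
place_proton_shift <- function(delta_h0, sw_h) {
  stopifnot(is.numeric(sw_h), sw_h > 0)
  0.2 * sw_h * tanh(6 * delta_h0 / sw_h) + 0.3 * sw_h * tanh(2 * delta_h0 / sw_h)
}

#' Multiplet modulation with roofing
#'
#' Time-domain modulation of one dimension by two active scalar couplings,
#' `{cos(pi*J1*t) + rho1*i*sin(pi*J1*t)} * {cos(pi*J2*t) + rho2*i*sin(pi*J2*t)}`,
#' evaluated at the effective coupling time `t + tau_coup`. The imaginary
#' `rho` terms model roofing (deviations from the weak-coupling limit);
#' with `rho = 0` each factor is a pure cosine, i.e. the symmetric
#' doublet/triplet phase pattern. Only phase evolves during `tau_coup`
#' (no relaxation is applied during the coupling delay).
#'
#' @param j1,j2 Active couplings in Hz (0 allowed; both 0 gives a singlet
#'   whose modulation is identically 1).
#' @param rho1,rho2 Unitless roofing factors.
#' @param t Evolution time(s) in seconds.
#' @param tau_coup Additional coupling evolution delay in seconds.
#' @return Complex modulation factor(s), same length as `t`.
#' @examples
#' multiplet_modulation(70, 0, 0, 0, t = 0, tau_coup = 2.3e-3)  # cos(pi*70*0.0023)
#' @export
multiplet_modulation <- function(j1, j2, rho1 = 0, rho2 = 0, t, tau_coup = 0) {
  stopifnot(all(t >= 0), tau_coup >= 0)
  te <- t + tau_coup
  (cos(pi * j1 * te) + rho1 * 1i * sin(pi * j1 * te)) *
    (cos(pi * j2 * te) + rho2 * 1i * sin(pi * j2 * te))
}

#' Residual solvent profile in the 1H frequency domain
#'
#' A sharp tail decaying from one edge of the 1H axis,
#' `10*amp*(slp*(1/(x+0.1) - 0.9) - (1-slp)*x)` evaluated at `x = i/n`,
#' `i = 0..n-1`, emulating a residual water signal. When `inverted`, the
#' profile is mirrored along the 1H axis so that solvent tails enter from
#' either side of the spectrum.
#'
#' @param amp Amplitude (drawn from the same distribution as peak
#'   intensities when simulating full planes).
#' @param slp Shape parameter in `[0, 1]`.
#' @param n Number of frequency points.
#' @param inverted Mirror the profile along the axis.
#' @return Real numeric vector of length `n`.
#' @examples
#' solvent_profile(1, 1, 8)[1]  # 10 * (1/0.1 - 0.9) = 91
#' @export
solvent_profile <- function(amp, slp, n, inverted = FALSE) {
  stopifnot(n >= 2)
  if (!is.numeric(slp) || slp < 0 || slp > 1) stop("'slp' must lie in [0, 1]")
  x <- (seq_len(n) - 1) / n
  p <- 10 * amp * (slp * (1 / (x + 0.1) - 0.9) - (1 - slp) * x)
  if (inverted) rev(p) else p
}

#' Simulator configuration
#'
#' All distribution parameters of the synthetic-data generator, exposed as a
#' plain list. Defaults encode the study conditions: 40-200 cross-peaks per
#' plane, 13C shifts uniform over the sweep width, 1H shifts squashed via
#' [place_proton_shift()], carbon couplings N(63, 10) Hz with 20%/20%
#' zeroing, proton couplings N(8, 2) / N(4, 2) Hz with 10%/50% zeroing,
#' roofing factors N(0, 0.08), input 13C relaxation N(50, 20) s^-1 with the
#' target rate exactly halved, intensities |N(1, 0.3)|, additive complex
#' Gaussian noise (SD a fraction of the maximum time-domain amplitude),
#' zero/first-order phase errors uniform within +/-5 degrees, and a residual
#' solvent tail inverted with probability 1/2.
#'
#' @param n_peaks_min,n_peaks_max Cross-peak count range (uniform draw).
#' @param sw_h,sw_c Sweep widths in Hz.
#' @param n_c_min,n_c_max,n_h_min,n_h_max Ranges for per-set complex point
#'   counts (uniform integer draws).
#' @param zf_c,zf_h Zero-fill targets (complex points).
#' @param tau_coup Coupling evolution delay of the second input plane (s).
#' @param r2c_mean,r2c_sd,r2c_min Input 13C transverse relaxation (s^-1);
#'   draws are truncated below at `r2c_min`.
#' @param r2h_mean,r2h_sd,r2h_min Same for 1H.
#' @param jc_mean,jc_sd,jc_pzero Carbon coupling distribution.
#' @param j1h_mean,j1h_sd,j1h_pzero,j2h_mean,j2h_sd,j2h_pzero Proton coupling
#'   distributions.
#' @param roof_sd SD of the roofing factors.
#' @param int_mean,int_sd Peak intensity distribution (absolute value of a
#'   normal draw).
#' @param noise_sd_frac Noise SD as a fraction of the maximum noiseless
#'   time-domain amplitude; 0 disables noise.
#' @param phase_max_deg Half-range of the uniform zero- and first-order
#'   phase errors, in degrees; 0 disables phase errors.
#' @param solvent Logical; include the residual solvent signal.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_peaks_min = 40, n_peaks_max = 200,
                       sw_h = 10000, sw_c = 5000,
                       n_c_min = 96, n_c_max = 200,
                       n_h_min = 128, n_h_max = 256,
                       zf_c = 200, zf_h = 256,
                       tau_coup = 2.3e-3,
                       r2c_mean = 50, r2c_sd = 20, r2c_min = 1,
                       r2h_mean = 50, r2h_sd = 20, r2h_min = 1,
                       jc_mean = 63, jc_sd = 10, jc_pzero = 0.2,
                       j1h_mean = 8, j1h_sd = 2, j1h_pzero = 0.1,
                       j2h_mean = 4, j2h_sd = 2, j2h_pzero = 0.5,
                       roof_sd = 0.08,
                       int_mean = 1, int_sd = 0.3,
                       noise_sd_frac = 1e-3,
                       phase_max_deg = 5,
                       solvent = TRUE) {
  cfg <- as.list(environment())
  if (cfg$n_peaks_min < 1 || cfg$n_peaks_max < cfg$n_peaks_min)
    stop("invalid cross-peak count range")
  if (cfg$n_c_max > cfg$zf_c || cfg$n_h_max > cfg$zf_h)
    stop("point-count ranges exceed the zero-fill targets")
  if (cfg$jc_pzero < 0 || cfg$jc_pzero > 1) stop("'jc_pzero' must be in [0,1]")
  if (cfg$noise_sd_frac < 0) stop("'noise_sd_frac' must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw one set of aromatic spin systems
#'
#' @param n Number of cross-peaks.
#' @param config A [sim_config()].
#' @return A data.frame, one row per cross-peak, with columns
#'   `delta_c`, `delta_h0`, `delta_h` (Hz), `intensity`, `r2c_in`, `r2c_tar`,
#'   `r2h` (s^-1), `j1c`, `j2c`, `j1h`, `j2h` (Hz), and roofing factors
#'   `rho1c`, `rho2c`, `rho1h`, `rho2h`.
#' @export
sample_spin_systems <- function(n, config = sim_config()) {
  jc <- sample_carbon_couplings(n, config$jc_mean, config$jc_sd, config$jc_pzero)
  j1h <- stats::rnorm(n, config$j1h_mean, config$j1h_sd)
  j1h[stats::runif(n) < config$j1h_pzero] <- 0
  j2h <- stats::rnorm(n, config$j2h_mean, config$j2h_sd)
  j2h[stats::runif(n) < config$j2h_pzero] <- 0
  delta_h0 <- stats::rnorm(n, 0, config$sw_h / 4)
  r2c_in <- pmax(stats::rnorm(n, config$r2c_mean, config$r2c_sd), config$r2c_min)
  data.frame(
    delta_c = stats::runif(n, -config$sw_c / 2, config$sw_c / 2),
    delta_h0 = delta_h0,
    delta_h = place_proton_shift(delta_h0, config$sw_h),
    intensity = abs(stats::rnorm(n, config$int_mean, config$int_sd)),
    r2c_in = r2c_in,
    r2c_tar = 0.5 * r2c_in,
    r2h = pmax(stats::rnorm(n, config$r2h_mean, config$r2h_sd), config$r2h_min),
    j1c = jc$j1, j2c = jc$j2,
    j1h = j1h, j2h = j2h,
    rho1c = stats::rnorm(n, 0, config$roof_sd),
    rho2c = stats::rnorm(n, 0, config$roof_sd),
    rho1h = stats::rnorm(n, 0, config$roof_sd),
    rho2h = stats::rnorm(n, 0, config$roof_sd)
  )
}

#' Multiplet class of each spin system
#'
#' Pure function of which carbon couplings are zero: `"singlet"` (both),
#' `"doublet"` (exactly one), `"triplet"` (none).
#'
#' @param systems Data frame from [sample_spin_systems()].
#' @return Character vector of classes.
#' @export
multiplet_class <- function(systems) {
  nz <- (systems$j1c != 0) + (systems$j2c != 0)
  c("singlet", "doublet", "triplet")[nz + 1L]
}

#' Synthesize one noiseless time-domain plane
#'
#' Sums, over spin systems, the separable hypercomplex FID
#' `intensity * exp(i*2*pi*delta_c*t1 - r2c*t1) * Mc(t1 + tau_coup)` in 13C
#' times `exp(i*2*pi*delta_h*t2 - r2h*t2) * Mh(t2)` in 1H, where `Mc`, `Mh`
#' are [multiplet_modulation()] factors. Modes:
#' \describe{
#'   \item{`input_nocoup`}{carbon multiplets, `tau_coup = 0`, input R2.}
#'   \item{`input_coup`}{carbon multiplets evolved for `acq$tau_coup`.}
#'   \item{`target`}{no carbon multiplet factor at all and the halved 13C
#'     relaxation rate `r2c_tar`; proton couplings are retained.}
#' }
#' Noise, phase errors and solvent are **not** added here; see
#' [generate_training_set()].
#'
#' @param systems Data frame of spin systems (possibly 0 rows).
#' @param acq An [acq_scheme()]; `acq$tau_coup` is used in `input_coup` mode.
#' @param mode One of `"input_nocoup"`, `"input_coup"`, `"target"`.
#' @return Complex array `dim = c(n_h, n_c, 2)`; the third index holds the
#'   cos/sin (real/imaginary) t1 quadrature components.
#' @export
synthesize_fid <- function(systems, acq,
                           mode = c("input_nocoup", "input_coup", "target")) {
  mode <- match.arg(mode)
  stopifnot(inherits(acq, "acq_scheme"))
  t1 <- acq_t1(acq)
  t2 <- acq_t2(acq)
  out <- array(0 + 0i, dim = c(acq$n_h, acq$n_c, 2))
  n <- nrow(systems)
  if (is.null(n) || n == 0L) return(out)
  if (any(abs(systems$delta_h) > 0.5 * acq$sw_h))
    stop("a 1H offset lies outside the sweep width; systems and scheme disagree")
  tau <- if (mode == "input_coup") acq$tau_coup else 0
  r2c <- if (mode == "target") systems$r2c_tar else systems$r2c_in
  # carbon-dimension signals, one column per system: (n_c x n)
  fc <- sapply(seq_len(n), function(k) {
    s <- systems[k, ]
    sig <- s$intensity * exp((2i * pi * s$delta_c - r2c[k]) * t1)
    if (mode != "target")
      sig <- sig * multiplet_modulation(s$j1c, s$j2c, s$rho1c, s$rho2c, t1, tau)
    sig
  })
  fh <- sapply(seq_len(n), function(k) {
    s <- systems[k, ]
    exp((2i * pi * s$delta_h - s$r2h) * t2) *
      multiplet_modulation(s$j1h, s$j2h, s$rho1h, s$rho2h, t2, 0)
  })
  fc <- matrix(fc, nrow = acq$n_c); fh <- matrix(fh, nrow = acq$n_h)
  out[, , 1] <- fh %*% t(Re(fc))
  out[, , 2] <- fh %*% t(Im(fc))
  out
}

# apply a (p0, p1) phase roll (radians) along one dimension of a plane
phase_roll <- function(plane, p0, p1, dim = c("h", "c")) {
  dim <- match.arg(dim)
  if (dim == "h") {
    n <- nrow(plane)
    ph <- exp(1i * (p0 + p1 * (seq_len(n) - 1) / n))
    plane[, , 1] <- plane[, , 1] * ph
    plane[, , 2] <- plane[, , 2] * ph
  } else {
    n <- dim(plane)[2]
    ph <- exp(1i * (p0 + p1 * (seq_len(n) - 1) / n))
    # rotate the t1 quadrature pair: (P1 + i P2) * ph
    z1 <- plane[, , 1]; z2 <- plane[, , 2]
    plane[, , 1] <- sweep(z1, 2, Re(ph), "*") - sweep(z2, 2, Im(ph), "*")
    plane[, , 2] <- sweep(z1, 2, Im(ph), "*") + sweep(z2, 2, Re(ph), "*")
  }
  plane
}

#' Generate one synthetic training set
#'
#' Draws a full random plane configuration (peak count uniform between the
#' configured bounds, per-set point counts, spin systems, solvent, noise and
#' phase errors) and synthesizes the triple (`input_nocoup`, `input_coup`,
#' `target`). The solvent tail and noise/phase imperfections are added to the
#' two input planes only; the target is the clean decoupled plane. The result
#' is fully reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; one generator stream per set.
#' @return An object of class `spectrum_set`: list with complex arrays
#'   `input_nocoup`, `input_coup`, `target` (`dim = c(n_h, n_c, 2)`) and a
#'   `params` list (spin systems, acquisition, solvent/noise/phase draws,
#'   seed).
#' @export
generate_training_set <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n_peaks <- sample(config$n_peaks_min:config$n_peaks_max, 1L)
  n_c <- sample(config$n_c_min:config$n_c_max, 1L)
  n_h <- sample(config$n_h_min:config$n_h_max, 1L)
  acq0 <- acq_scheme(config$sw_h, config$sw_c, n_c, n_h, 0,
                     config$zf_c, config$zf_h)
  acq1 <- acq_scheme(config$sw_h, config$sw_c, n_c, n_h, config$tau_coup,
                     config$zf_c, config$zf_h)
  systems <- sample_spin_systems(n_peaks, config)

  inp0 <- synthesize_fid(systems, acq0, "input_nocoup")
  inp1 <- synthesize_fid(systems, acq1, "input_coup")
  target <- synthesize_fid(systems, acq0, "target")

  solv <- NULL
  if (isTRUE(config$solvent)) {
    solv <- list(amp = abs(stats::rnorm(1, config$int_mean, config$int_sd)),
                 slp = stats::runif(1),
                 inverted = stats::runif(1) < 0.5)
    prof <- solvent_profile(solv$amp, solv$slp, n_h, solv$inverted)
    # inverse FT of the frequency profile -> 1H time-domain trace, added
    # uniformly along t1 (cos component): a ridge at the 13C carrier
    st <- stats::fft(as.complex(prof), inverse = TRUE) / n_h
    inp0[, , 1] <- inp0[, , 1] + st
    inp1[, , 1] <- inp1[, , 1] + st
  }

  deg <- pi / 180
  phases <- list()
  for (nm in c("input_nocoup", "input_coup")) {
    p <- stats::runif(4, -config$phase_max_deg, config$phase_max_deg) * deg
    phases[[nm]] <- list(h = p[1:2], c = p[3:4])
  }
  if (config$phase_max_deg > 0) {
    inp0 <- phase_roll(inp0, phases$input_nocoup$h[1], phases$input_nocoup$h[2], "h")
    inp0 <- phase_roll(inp0, phases$input_nocoup$c[1], phases$input_nocoup$c[2], "c")
    inp1 <- phase_roll(inp1, phases$input_coup$h[1], phases$input_coup$h[2], "h")
    inp1 <- phase_roll(inp1, phases$input_coup$c[1], phases$input_coup$c[2], "c")
  }

  noise_sd <- 0
  if (config$noise_sd_frac > 0) {
    amp_max <- max(Mod(inp0), Mod(inp1))
    noise_sd <- config$noise_sd_frac * amp_max
    rn <- function() {
      array(complex(real = stats::rnorm(n_h * n_c * 2, 0, noise_sd),
                    imaginary = stats::rnorm(n_h * n_c * 2, 0, noise_sd)),
            dim = c(n_h, n_c, 2))
    }
    inp0 <- inp0 + rn()
    inp1 <- inp1 + rn()
  }

  structure(list(
    input_nocoup = inp0,
    input_coup = inp1,
    target = target,
    params = list(systems = systems, acq = acq1, acq_nocoup = acq0,
                  solvent = solv, noise_sd = noise_sd, phases = phases,
                  seed = as.integer(seed))
  ), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  a <- x$params$acq
  cat(sprintf("synthetic spectrum set: %d cross-peaks, %d x %d complex points (1H x 13C), seed %d\n",
              nrow(x$params$systems), a$n_h, a$n_c, x$params$seed))
  invisible(x)
}
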