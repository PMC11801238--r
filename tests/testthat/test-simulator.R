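test_that("carbon coupling sampling follows the zeroing law", {
  set.seed(101)
  # forced zeroing gives pure singlets
  j <- sample_carbon_couplings(50, p_zero = 1)
  expect_true(all(j$j1 == 0) && all(j$j2 == 0))

  n <- 1e5
  j <- sample_carbon_couplings(n)
  nz <- (j$j1 != 0) + (j$j2 != 0)
  fr <- c(triplet = mean(nz == 2), doublet = mean(nz == 1), singlet = mean(nz == 0))
  exp_fr <- c(0.8^2, 2 * 0.8 * 0.2, 0.2^2)
  tol <- 3 * sqrt(exp_fr * (1 - exp_fr) / n)
  expect_true(all(abs(fr - exp_fr) < tol))

  # nonzero couplings keep the stated normal location
  nzj <- c(j$j1[j$j1 != 0], j$j2[j$j2 != 0])
  expect_lt(abs(mean(nzj) - 63), 3 * 10 / sqrt(length(nzj)))

  expect_error(sample_carbon_couplings(5, p_zero = 1.2), "probability")
  expect_error(sample_carbon_couplings(5, sd = -1), "non-negative")
})

test_that("proton shift placement is odd, bounded, and matches the closed form", {
  expect_identical(place_proton_shift(0, 8000), 0)
  # frozen regression value: 0.2*sw*tanh(6*d0/sw) + 0.3*sw*tanh(2*d0/sw)
  # evaluated independently at d0 = sw/4, sw = 8000
  expect_equal(place_proton_shift(2000, 8000), 2557.31838326, tolerance = 1e-10)
  # tanh saturation: approaches half the sweep width but stays inside it
  expect_lt(place_proton_shift(2 * 8000, 8000), 4000)
  expect_equal(place_proton_shift(1e9, 8000), 4000, tolerance = 1e-6)
  set.seed(7)
  d0 <- rnorm(1000, 0, 2000)
  dh <- place_proton_shift(d0, 8000)
  expect_true(all(abs(dh) < 4000))
  expect_equal(dh, -place_proton_shift(-d0, 8000))
})

test_that("multiplet modulation reproduces the coupling phase patterns", {
  t <- seq(0, 0.02, length.out = 11)
  # singlet: no evolution regardless of the coupling delay
  expect_equal(multiplet_modulation(0, 0, 0.05, -0.03, t, 2.3e-3),
               rep(1 + 0i, 11))
  # zero total evolution time
  expect_equal(multiplet_modulation(70, 55, 0.1, 0.1, 0, 0), 1 + 0i)
  # doublet phase at t = 0 after the 2.3 ms delay: cos(pi*70*0.0023)
  expect_equal(multiplet_modulation(70, 0, 0, 0, 0, 2.3e-3),
               0.874788884333 + 0i, tolerance = 1e-10)
  # with rho = 0 each factor is the pure cosine product
  expect_equal(multiplet_modulation(63, 40, 0, 0, t, 1e-3),
               as.complex(cos(pi * 63 * (t + 1e-3)) * cos(pi * 40 * (t + 1e-3))))
})

test_that("solvent profile has the stated edge value and mirror contract", {
  expect_equal(solvent_profile(0, 0.5, 64), rep(0, 64))
  p <- solvent_profile(1.3, 0.7, 128)
  expect_equal(solvent_profile(1.3, 0.7, 128, inverted = TRUE), rev(p))
  # frozen value at x = 0 with amp = 1, slp = 1: 10*(1/0.1 - 0.9) = 91
  expect_equal(solvent_profile(1, 1, 256)[1], 91)
  expect_error(solvent_profile(1, 1.5, 16), "slp")
})

test_that("synthesized FIDs obey the mode contracts", {
  acq <- acq_scheme(n_c = 16, n_h = 16, zf_c = 16, zf_h = 16, tau_coup = 2.3e-3)
  # empty system list: zero plane
  empty <- synthesize_fid(singlet_system()[0, ], acq)
  expect_true(all(empty == 0))

  # a singlet is blind to the coupling delay: the two input planes agree
  sys <- singlet_system(delta_c = 400, delta_h = -300)
  p0 <- synthesize_fid(sys, acq, "input_nocoup")
  p1 <- synthesize_fid(sys, acq, "input_coup")
  expect_equal(p0, p1)

  # first FID point (t1 = t2 = 0, cos component) = summed intensities
  set.seed(3)
  cfg <- clean_sim()
  systems <- sample_spin_systems(6, cfg)
  pl <- synthesize_fid(systems, acq, "input_nocoup")
  expect_equal(Re(pl[1, 1, 1]), sum(systems$intensity), tolerance = 1e-12)
  expect_equal(pl[1, 1, 2], 0 + 0i)

  # target relaxation halving is exact for every generated system
  expect_equal(systems$r2c_tar, 0.5 * systems$r2c_in)

  expect_error(synthesize_fid(singlet_system(delta_h = 9000), acq), "sweep width")
})

test_that("a 63 Hz doublet transforms into two lines ~63 Hz apart", {
  acq <- acq_scheme(n_c = 128, n_h = 16, zf_c = 128, zf_h = 16)
  sys <- singlet_system(delta_c = 800, delta_h = 0)
  sys$j1c <- 63
  fid <- synthesize_fid(sys, acq, "input_nocoup")
  sp <- process_plane(fid, acq, window = NULL)
  prof <- sp$spec[which.min(abs(sp$axis_h)), ]
  pk <- sort(sp$axis_c[order(prof, decreasing = TRUE)[1:2]])
  dig <- diff(sp$axis_c)[1]
  expect_lt(abs(diff(pk) - 63), dig + 1e-9)        # split within one digital point
  expect_lt(abs(mean(pk) - 800), dig + 1e-9)       # centred on the 13C offset
})

test_that("clean sets reduce to the relaxation-halving relation between planes", {
  cfg <- clean_sim(jc_pzero = 1, j1h_pzero = 1, j2h_pzero = 1)
  set <- generate_training_set(cfg, seed = 21)
  # all couplings zero, no noise: the two inputs are identical
  expect_equal(set$input_nocoup, set$input_coup)
  # and the target equals the input re-synthesized with halved 13C relaxation
  sys2 <- set$params$systems
  sys2$r2c_in <- sys2$r2c_tar
  rebuilt <- synthesize_fid(sys2, set$params$acq_nocoup, "input_nocoup")
  expect_equal(set$target, rebuilt, tolerance = 1e-12)
})

test_that("training-set generation is seed-reproducible with lawful statistics", {
  cfg <- tiny_sim()
  s1 <- generate_training_set(cfg, seed = 11)
  s2 <- generate_training_set(cfg, seed = 11)
  expect_identical(s1, s2)
  expect_false(identical(s1$input_nocoup,
                         generate_training_set(cfg, seed = 12)$input_nocoup))

  nsets <- 400
  counts <- integer(nsets); inv <- logical(nsets)
  for (k in seq_len(nsets)) {
    st <- generate_training_set(cfg, seed = 5000 + k)
    counts[k] <- nrow(st$params$systems)
    inv[k] <- st$params$solvent$inverted
  }
  # peak count uniform on the configured range
  rng <- cfg$n_peaks_min:cfg$n_peaks_max
  expect_true(all(counts %in% rng))
  p <- chisq.test(tabulate(counts - cfg$n_peaks_min + 1L, length(rng)))$p.value
  expect_gt(p, 0.01)
  # half of the solvent tails are inverted
  expect_lt(abs(mean(inv) - 0.5), 3 * sqrt(0.25 / nsets))
})

test_that("every plane in a set shares shape and the peak count honors its bounds", {
  cfg <- tiny_sim()
  st <- generate_training_set(cfg, seed = 33)
  expect_identical(dim(st$input_nocoup), dim(st$input_coup))
  expect_identical(dim(st$input_coup), dim(st$target))
  n <- nrow(st$params$systems)
  expect_gte(n, cfg$n_peaks_min); expect_lte(n, cfg$n_peaks_max)
  cls <- multiplet_class(st$params$systems)
  expect_true(all(cls %in% c("singlet", "doublet", "triplet")))
})
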