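test_that("the forward ZZ model honors its limiting cases", {
  p <- exchange_params(3.39, 0.363, r1_f = 2, r1_u = 2.5, amp_f = 2, amp_u = 1)
  # no evolution at zero mixing time
  f0 <- zz_forward(p, 0)
  expect_equal(unlist(f0[, c("FF", "UU", "FU", "UF")]),
               c(FF = 2, UU = 1, FU = 0, UF = 0))
  # no exchange: pure mono-exponential diagonal decay, no cross-peaks
  pne <- exchange_params(0, 0.4, r1_f = 3, r1_u = 1, amp_f = 1, amp_u = 1)
  t <- c(0.05, 0.2, 0.4)
  fne <- zz_forward(pne, t)
  expect_equal(fne$FF, exp(-3 * t))
  expect_equal(fne$UU, exp(-1 * t))
  expect_true(all(fne$FU == 0) && all(fne$UF == 0))
})

test_that("magnetization is conserved and symmetric under matched relaxation", {
  p <- exchange_params(5, 0.3, r1_f = 0, r1_u = 0, amp_f = 1, amp_u = 1)
  t <- seq(0, 2, by = 0.1)
  f <- zz_forward(p, t)
  # without relaxation the total from each source is conserved
  expect_equal(f$FF + f$FU, rep(1, length(t)))
  expect_equal(f$UU + f$UF, rep(1, length(t)))
  # detailed-balance symmetry: with matched relaxation and amplitudes
  # proportional to the populations, the two cross-peak curves coincide
  p2 <- exchange_params(4, 0.25, r1_f = 1.3, r1_u = 1.3)
  f2 <- zz_forward(p2, t)
  expect_equal(f2$FU, f2$UF)
  # equivalently, the propagator off-diagonals scale as the exchange rates
  E <- aromadec:::expm2(aromadec:::exchange_rate_matrix(p2), 0.2)
  expect_equal(E[2, 1] / E[1, 2], (4 * 0.25) / (4 * 0.75))
  # cross-peaks start at zero and are unimodal with positive relaxation
  p3 <- exchange_params(3.39, 0.363, r1_f = 2, r1_u = 2)
  fu <- zz_forward(p3, seq(0, 3, by = 0.01))$FU
  expect_equal(fu[1], 0)
  expect_equal(sum(diff(sign(diff(fu))) != 0), 1)
})

test_that("long-time source-resolved magnetization reaches the population partition", {
  # relaxation-free evolution from either source ends at (1 - p_u, p_u)
  p <- exchange_params(3.39, 0.363, r1_f = 0, r1_u = 0, amp_f = 1, amp_u = 1)
  f <- zz_forward(p, 50)
  expect_equal(c(f$FF, f$FU), c(1 - 0.363, 0.363), tolerance = 1e-6)
  expect_equal(c(f$UF, f$UU), c(1 - 0.363, 0.363), tolerance = 1e-6)
})

test_that("the analytic propagator matches the dense matrix exponential", {
  set.seed(31)
  for (i in 1:8) {
    p <- exchange_params(runif(1, 0.1, 10), runif(1, 0.05, 0.95),
                         runif(1, 0, 5), runif(1, 0, 5))
    K <- aromadec:::exchange_rate_matrix(p)
    tt <- runif(1, 0, 1)
    expect_equal(aromadec:::expm2(K, tt), as.matrix(Matrix::expm(K * tt)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("noiseless datasets refit to the generating parameters", {
  delays <- c(25, 50, 100, 150, 200, 250, 300) / 1000
  truth <- exchange_params(3.39, 0.363, r1_f = 2.0, r1_u = 2.5)
  fit <- fit_exchange(simulate_exchange_dataset(truth, delays, 0))
  expect_lt(abs(fit$coef[["k_ex"]] - 3.39) / 3.39, 1e-3)
  expect_lt(abs(fit$coef[["p_u"]] - 0.363) / 0.363, 1e-3)
  expect_lt(abs(fit$coef[["r1_f"]] - 2.0) / 2.0, 1e-3)

  delays15 <- c(25, 25, 50, 100, 150, 200, 200, 250, 300, 400, 600, 800) / 1000
  truth15 <- exchange_params(4.08, 0.387, r1_f = 1.2, r1_u = 1.5)
  fit15 <- fit_exchange(simulate_exchange_dataset(truth15, delays15, 0))
  expect_lt(abs(fit15$coef[["k_ex"]] - 4.08) / 4.08, 1e-3)
  expect_lt(abs(fit15$coef[["p_u"]] - 0.387) / 0.387, 1e-3)
})

test_that("zero cross-peaks drive the fitted exchange rate to the floor", {
  delays <- c(25, 50, 100, 150, 200, 250, 300) / 1000
  d <- simulate_exchange_dataset(exchange_params(1, 0.4, 1.5, 1.5), delays, 0)
  d$intensity[d$class %in% c("FU", "UF")] <- 0
  d$intensity[d$class == "FF"] <- 0.6 * exp(-1.5 * delays)
  d$intensity[d$class == "UU"] <- 0.4 * exp(-1.5 * delays)
  fit <- fit_exchange(d)
  expect_lt(fit$coef[["k_ex"]], 1e-4)
})

test_that("simulated datasets are reproducible and exact when noiseless", {
  p <- exchange_params(2, 0.3, 1, 1)
  delays <- c(0.05, 0.1, 0.2)
  d0 <- simulate_exchange_dataset(p, delays, 0)
  fwd <- zz_forward(p, delays)
  expect_equal(d0$intensity, c(fwd$FF, fwd$UU, fwd$FU, fwd$UF))
  dn1 <- simulate_exchange_dataset(p, delays, 0.01, seed = 5)
  dn2 <- simulate_exchange_dataset(p, delays, 0.01, seed = 5)
  expect_identical(dn1, dn2)
  expect_error(exchange_params(3, 1.2), "p_u")
  expect_error(fit_exchange(data.frame(delay = 0.1, class = "FF", intensity = 1)),
               "two or more delays")
})

test_that("bootstrap and covariance uncertainties are produced", {
  delays <- c(25, 50, 100, 150, 200, 250, 300) / 1000
  truth <- exchange_params(3.39, 0.363, r1_f = 2, r1_u = 2.5)
  mx <- max(zz_forward(truth, delays)[, c("FF", "UU")])
  d <- simulate_exchange_dataset(truth, delays, noise_sd = 0.02 * mx, seed = 2)
  fit <- fit_exchange(d, bootstrap = 20, seed = 3)
  expect_true(all(is.finite(fit$se[c("k_ex", "p_u")])))
  expect_true(all(is.finite(fit$boot_se[c("k_ex", "p_u")])))
  # the two error routes agree in order of magnitude
  expect_lt(fit$boot_se[["k_ex"]] / fit$se[["k_ex"]], 10)
  expect_gt(fit$boot_se[["k_ex"]] / fit$se[["k_ex"]], 0.1)
})
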