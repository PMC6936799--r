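test_that("observation volume has the closed form and scales as length^3", {
  opt <- optical_config(0.25, 1.25)
  expect_equal(observation_volume(opt), (pi / 2)^1.5 * 0.25^2 * 1.25)
  # direct evaluation for unequal channels
  opt2 <- opt_uneq()
  expect_equal(observation_volume(opt2),
               (pi / 2)^1.5 * ((0.25^2 + 0.3^2) / 2) * sqrt((1.25^2 + 1^2) / 2))
  # doubling all lengths multiplies the volume by 8
  opt3 <- optical_config(0.5, 2.5, 0.6, 2.0)
  expect_equal(observation_volume(opt3), 8 * observation_volume(opt2))
  expect_error(optical_config(-0.1, 1), "positive")
})

test_that("shape factors match (m+n)^(-3/2) for identical channels", {
  opt <- opt_eq()
  g <- expand.grid(m = 0:4, n = 0:4)
  g <- g[g$m + g$n >= 1, ]
  expect_equal(shape_factor(g$m, g$n, opt), (g$m + g$n)^-1.5)
  expect_equal(round(shape_factor(3, 0, opt), 3), 0.192)
  expect_equal(shape_factor(4, 0, opt), 0.125)
  expect_error(shape_factor(0, 0, opt))
})

test_that("shape factors for unequal channels match quadrature of the defining integral", {
  opt <- opt_uneq()
  for (mn in list(c(1, 0), c(1, 1), c(2, 1), c(2, 2), c(3, 1)))
    expect_equal(shape_factor(mn[1], mn[2], opt),
                 gamma_quadrature(mn[1], mn[2], opt), tolerance = 1e-9)
})

test_that("diffusion factor has the right limits and closed form at (1,1)", {
  opt <- opt_eq(r = 0.25, s = 4)
  g <- expand.grid(m = 0:4, n = 0:4)
  g <- g[g$m + g$n >= 1, ]
  expect_equal(diffusion_factor(g$m, g$n, 0, 100, opt), rep(1, nrow(g)))
  # m = n = 1 reduces to the standard FCS Lorentzian-type form
  D <- 80; tau <- 2e-4
  tau_d <- 0.25^2 / (4 * D)
  expect_equal(diffusion_factor(1, 1, tau, D, opt),
               (1 + tau / tau_d)^-1 * (1 + tau / (16 * tau_d))^-0.5)
  expect_lt(diffusion_factor(1, 1, 100, D, opt), 1e-6)
  # non-increasing in tau, for several orders
  taus <- 10^seq(-6, -1, length.out = 30)
  for (mn in list(c(1, 1), c(2, 1), c(2, 2), c(3, 1)))
    expect_true(all(diff(diffusion_factor(mn[1], mn[2], taus, D, opt)) <= 0))
  # orders with m or n zero carry no tau dependence
  expect_equal(diffusion_factor(3, 0, taus, D, opt), rep(1, 30))
  expect_error(diffusion_factor(1, 1, -1, D, opt), "non-negative")
})

test_that("diffusion and flow factors match the lagged correlation integral", {
  opt <- opt_uneq()
  D <- 60; tau <- 1.5e-4
  for (mn in list(c(1, 1), c(2, 1), c(2, 3))) {
    m <- mn[1]; n <- mn[2]
    want <- kappa_dim_quadrature(m, n, tau, D, opt$r_A, opt$r_B)^2 *
      kappa_dim_quadrature(m, n, tau, D, opt$z_A, opt$z_B)
    expect_equal(diffusion_factor(m, n, tau, D, opt), want, tolerance = 1e-7)
  }
  # flow factor from the same integral with a drift
  v <- 400
  for (mn in list(c(1, 1), c(2, 1))) {
    m <- mn[1]; n <- mn[2]
    base <- kappa_dim_quadrature(m, n, tau, D, opt$r_A, opt$r_B)
    drift <- kappa_dim_quadrature(m, n, tau, D, opt$r_A, opt$r_B, v = v)
    expect_equal(flow_factor(m, n, tau, D, v, 0, opt), drift / base,
                 tolerance = 1e-6)
  }
})

test_that("flow factor is 1 without flow and decays monotonically in speed", {
  opt <- opt_eq()
  expect_equal(flow_factor(2, 2, 1e-4, 50, 0, 0, opt), 1)
  vs <- seq(0, 5000, length.out = 20)
  S <- flow_factor(1, 1, 2e-4, 50, vs, 0, opt)
  expect_true(all(diff(S) < 0))
  expect_lt(S[20], 1e-3)
})

test_that("correlation function combines brightness, shape and diffusion factors", {
  opt <- opt_eq()
  sp <- dim_species(eps = 0.7, tau_d = 50e-6)
  # G_{1,0} is tau-independent
  expect_equal(correlation_G(1, 0, c(0, 1e-4, 1e-2), sp, opt),
               rep(0.7 * shape_factor(1, 0, opt), 3))
  expect_equal(correlation_G(1, 1, 0, sp, opt), 0.7^2 * shape_factor(1, 1, opt))
  D <- opt$r_A^2 / (4 * 50e-6)
  expect_equal(correlation_G(2, 1, 3e-5, sp, opt),
               0.7^3 * shape_factor(2, 1, opt) *
                 diffusion_factor(2, 1, 3e-5, D, opt))
})

test_that("B2 matches the defining quadrature and has the right limits", {
  # limit alpha -> 0
  expect_equal(binning_B2(1e-6 * 50e-6, 50e-6, 0.25), 1, tolerance = 1e-4)
  # strictly decreasing in alpha
  alphas <- 10^seq(-3, 2, length.out = 40)
  for (beta in c(0.04, 0.25))
    expect_true(all(diff(binning_B2(alphas * 1e-4, 1e-4, beta)) < 0))
  # quadrature agreement
  for (beta in c(0.04, 0.25, 0.9))
    for (alpha in c(1e-3, 0.03, 1, 30))
      expect_equal(binning_B2(alpha * 2e-4, 2e-4, beta),
                   B2_quadrature(alpha, beta), tolerance = 1e-6)
  expect_error(binning_B2(1e-5, 1e-4, 1.5), "beta")
})

test_that("higher-order binning functions follow the product-of-B2 form", {
  b <- binning_B2(1e-4, 5e-5, 0.1)
  bB <- binning_B2(1e-4, 8e-5, 0.1)
  expect_equal(binning_Bmn(1, 0, 1e-4, 5e-5, beta_A = 0.1), 1)
  expect_equal(binning_Bmn(0, 1, 1e-4, 5e-5, beta_A = 0.1), 1)
  expect_equal(binning_Bmn(1, 1, 1e-4, 5e-5, beta_A = 0.1), 1)
  expect_equal(binning_Bmn(3, 0, 1e-4, 5e-5, beta_A = 0.1), b^2)
  expect_equal(binning_Bmn(2, 2, 1e-4, 5e-5, tau_B = 8e-5, beta_A = 0.1), b * bB)
})

test_that("factorial cumulants compose species, background and binning", {
  opt <- opt_eq()
  m1 <- dim_model(N = 3, eps = 0.4, tau_d = 50e-6, opt = opt)
  # single species, first order: N eps gamma_{1,0}
  expect_equal(factorial_cumulant(1, 0, 0, 1e-5, m1), 3 * 0.4)
  # background enters only at first order
  mbg <- dim_model(N = 3, eps = 0.4, tau_d = 50e-6, opt = opt,
                   lambda_A = 0.1, lambda_B = 0.05)
  expect_equal(factorial_cumulant(1, 0, 0, 1e-5, mbg), 3 * 0.4 + 0.1)
  expect_equal(factorial_cumulant(0, 1, 0, 1e-5, mbg), 3 * 0.4 + 0.05)
  expect_equal(factorial_cumulant(2, 2, 1e-5, 1e-5, mbg),
               factorial_cumulant(2, 2, 1e-5, 1e-5, m1))
  # two species at tau = 0: gamma_n (N1 eps1^n + N2 eps2^n) with tiny T
  # (so that binning corrections vanish)
  Tt <- 1e-12
  m2 <- cpch_model(opt, list(
    species_params(3, 0.4 / Tt, tau_d = 50e-6),
    species_params(2, 0.8 / Tt, tau_d = 200e-6)), T_ref = Tt)
  for (n in 1:4)
    expect_equal(factorial_cumulant(n, 0, 0, Tt, m2),
                 n^-1.5 * (3 * 0.4^n + 2 * 0.8^n), tolerance = 1e-6)
})

test_that("FCS consistency: 1 + K11/(K10 K01) is the classical closed form", {
  opt <- opt_eq(r = 0.2, s = 3)
  m <- dim_model(N = 4, eps = 0.3, tau_d = 80e-6, opt = opt)
  taus <- c(1e-6, 1e-5, 1e-4, 1e-3)
  Tt <- 1e-9  # negligible binning
  m$T_ref <- Tt
  m$species[[1]]$eps_A <- m$species[[1]]$eps_B <- 0.3 / Tt
  k11 <- factorial_cumulant(1, 1, taus, Tt, m)
  k10 <- factorial_cumulant(1, 0, taus, Tt, m)
  k01 <- factorial_cumulant(0, 1, taus, Tt, m)
  G <- 1 + k11 / (k10 * k01)
  want <- 1 + (2^-1.5 / 4) * (1 + taus / 80e-6)^-1 *
    (1 + taus / (9 * 80e-6))^-0.5
  expect_equal(G, want, tolerance = 1e-12)
})

test_that("bin schemes validate clock consistency", {
  bs <- bin_scheme(tau = c(0, 2e-5, 4e-5), T = 1e-5, sampling_time = 5e-8)
  expect_equal(bs$tau_k, c(0L, 2L, 4L))
  expect_equal(bs$T_s, rep(200L, 3))
  expect_error(bin_scheme(1.5e-5, 1e-5, 5e-8), "multiple")
  expect_error(bin_scheme(2e-5, 1.7e-8, 5e-8), "multiple")
})
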