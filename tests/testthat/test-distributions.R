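test_that("a dark molecule gives a delta distribution at (0,0)", {
  sp <- species_params(1, 0, D = 100)
  p1 <- p1_series(sp, opt_eq(), 1e-5, 1e-5, max_counts = 5)
  expect_equal(p1$values[1, 1], 1)
  expect_equal(sum(p1$values), 1)
})

test_that("the single-molecule marginal equals the 1D PCH integral", {
  # sum over n_y of p1(n_x, n_y | tau) is the classical single-molecule PCH
  # (1/V) int I^n exp(-I)/n! dx, independent of tau; V_AB/V = 1 convention
  opt <- opt_eq(r = 0.25, s = 5)
  eps <- 0.7
  sp <- species_params(1, eps, eps_unit = "counts_per_bin", tau_d = 50e-6)
  pch_int <- function(n) {
    Vab <- observation_volume(opt)
    radial <- function(rho, z)
      (eps * exp(-2 * rho^2 / opt$r_A^2 - 2 * z^2 / opt$z_A^2))^n *
        exp(-eps * exp(-2 * rho^2 / opt$r_A^2 - 2 * z^2 / opt$z_A^2)) *
        2 * pi * rho / factorial(n)
    f <- function(z) vapply(z, function(zz)
      stats::integrate(radial, 0, 6, z = zz, rel.tol = 1e-10)$value, 0)
    stats::integrate(f, -30, 30, rel.tol = 1e-9)$value / Vab
  }
  for (tau in c(25e-6, 250e-6)) {
    p1 <- p1_series(sp, opt, tau, 1e-9, max_counts = 12)
    marg <- rowSums(p1$values)
    for (n in 1:4) expect_equal(marg[n + 1], pch_int(n), tolerance = 1e-4)
  }
})

test_that("p1 series matches a Monte-Carlo evaluation on a dim case", {
  set.seed(99)
  opt <- opt_eq(r = 0.25, s = 2)
  eps <- 0.6; tau <- 6e-5; D <- opt$r_A^2 / (4 * 5e-5)
  sp <- species_params(1, eps, eps_unit = "counts_per_bin", D = D)
  p1 <- p1_series(sp, opt, tau, 1e-9, max_counts = 8)
  # sample a molecule uniformly in a box, diffuse it for tau, emit Poisson
  # photons at both times; estimate joint probabilities on V_AB/V = 1 scale
  nmc <- 2e6
  box <- c(3, 3, 6)
  V <- prod(box); Vab <- observation_volume(opt)
  x <- cbind(runif(nmc, -1.5, 1.5), runif(nmc, -1.5, 1.5), runif(nmc, -3, 3))
  y <- x + matrix(rnorm(3 * nmc, sd = sqrt(2 * D * tau)), ncol = 3)
  I <- function(p) eps * exp(-2 * (p[, 1]^2 + p[, 2]^2) / opt$r_A^2 -
                               2 * p[, 3]^2 / opt$z_A^2)
  nx <- rpois(nmc, I(x)); ny <- rpois(nmc, I(y))
  # MC estimates carry the physical 1/V; the series uses V_AB/V = 1, i.e.
  # probabilities conditioned on scale V_AB. Off-diagonal entries compare
  # directly after rescaling by V/V_AB.
  for (cell in list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))) {
    mc <- mean(nx == cell[1] & ny == cell[2]) * V / Vab
    se <- sqrt(mc * V / Vab / nmc) + 1e-8
    expect_lt(abs(p1$values[cell[1] + 1, cell[2] + 1] - mc), 5 * se)
  }
})

test_that("background-only models give product-Poisson distributions", {
  opt <- opt_eq()
  m <- cpch_model(opt, species_params(0, 1e4, D = 100), T_ref = 1e-5,
                  lambda_A = 0.8, lambda_B = 0.3)
  p <- pN_fft(m, 1e-5, 1e-5)
  want <- outer(dpois(0:(nrow(p$values) - 1), 0.8),
                dpois(0:(ncol(p$values) - 1), 0.3))
  expect_equal(p$values, want, tolerance = 1e-9)
  # N -> 0 with no background: delta at the origin
  m0 <- cpch_model(opt, species_params(0, 1e4, D = 100), T_ref = 1e-5)
  p0 <- pN_fft(m0, 1e-5, 1e-5, L_t = 4, L_s = 4)
  expect_equal(p0$values[1, 1], 1)
})

test_that("the recursion seed matches the closed form at (0,0)", {
  m <- dim_model(N = 2.5, eps = 0.5, lambda_A = 0.2, lambda_B = 0.1)
  p1 <- p1_series(m$species[[1]], m$optical, 5e-5, 1e-5, max_counts = 25)
  p <- pN_recursion(m, 5e-5, 1e-5, max_counts = 25)
  expect_equal(p$values[1, 1],
               exp(-2.5 * (1 - p1$values[1, 1]) - 0.2 - 0.1), tolerance = 1e-12)
})

test_that("series+FFT and recursion routes agree across a parameter grid", {
  for (N in c(0.1, 1, 25)) for (eps in c(0.1, 1)) for (ratio in c(0.1, 1, 10)) {
    tau_d <- 50e-6
    m <- dim_model(N = N, eps = eps, tau_d = tau_d)
    tau <- ratio * tau_d
    a <- pN_fft(m, tau, 1e-5)
    L <- min(nrow(a$values), 40)
    b <- pN_recursion(m, tau, 1e-5, max_counts = L - 1)
    pa <- a$values[1:L, 1:L]; pb <- b$values[1:L, 1:L]
    sel <- pa > 1e-12
    expect_lt(max(abs(pa[sel] - pb[sel])), 1e-9)
  }
})

test_that("channels decorrelate at large lags", {
  m <- dim_model(N = 1, eps = 0.8, tau_d = 50e-6)
  p <- pN_fft(m, 1, 1e-5)
  want <- outer(pch_marginal(p, 1), pch_marginal(p, 2))
  expect_lt(max(abs(p$values - want)), 1e-6)
})

test_that("a mixture distribution is the convolution of its species", {
  opt <- opt_eq()
  s1 <- species_params(2, 0.5 / 1e-5, tau_d = 50e-6)
  s2 <- species_params(1, 1.0 / 1e-5, tau_d = 200e-6)
  L <- 32
  pa <- pN_fft(cpch_model(opt, s1, T_ref = 1e-5), 5e-5, 1e-5, L, L)$values
  pb <- pN_fft(cpch_model(opt, s2, T_ref = 1e-5), 5e-5, 1e-5, L, L)$values
  pab <- pN_fft(cpch_model(opt, list(s1, s2), T_ref = 1e-5), 5e-5, 1e-5,
                L, L)$values
  pad <- function(p) rbind(cbind(p, matrix(0, L, L)), matrix(0, L, 2 * L))
  conv <- Re(stats::fft(stats::fft(pad(pa)) * stats::fft(pad(pb)),
                        inverse = TRUE)) / (2 * L)^2
  expect_equal(pab, conv[1:L, 1:L], tolerance = 1e-12)
})

test_that("PMF normalisation and non-negativity hold after the FFT route", {
  for (N in c(0.3, 5)) for (eps in c(0.2, 1.2)) {
    p <- pN_fft(dim_model(N = N, eps = eps), 2e-5, 1e-5)
    expect_equal(sum(p$values), 1, tolerance = 1e-6)
    expect_true(all(p$values >= 0))
    expect_lt(p$clip, 1e-6)
  }
})

test_that("dual-colour zero-lag distributions behave per channel layout", {
  opt <- opt_eq()
  # species visible only in channel A: joint factorises
  s <- species_params(1.5, 0.6 / 1e-5, 0, tau_d = 50e-6)
  m <- cpch_model(opt, s, T_ref = 1e-5, lambda_B = 0.2)
  p <- dual_color_pch(m, 1e-5)
  want <- outer(pch_marginal(p, 1), pch_marginal(p, 2))
  expect_equal(p$values, want, tolerance = 1e-10)
  expect_equal(p$tau, 0)
  # single channel at zero lag: diagonal-only, diagonal is the PCH
  m1 <- dim_model(N = 1, eps = 0.5)
  expect_warning(pd <- dual_color_pch(m1, 1e-5, single_channel = TRUE,
                                      max_counts = 15), "diagonal")
  off <- pd$values; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
  pch <- pch_marginal(pN_fft(m1, 5e-5, 1e-5), 1)
  expect_equal(diag(pd$values)[1:10], pch[1:10], tolerance = 1e-9)
})

test_that("the series route reports non-convergence for very bright molecules", {
  sp <- species_params(1, 80, eps_unit = "counts_per_bin", tau_d = 50e-6)
  expect_error(p1_series(sp, opt_eq(), 1e-5, 1e-5, max_counts = 10, k_cap = 60),
               "FFT|converge")
})
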