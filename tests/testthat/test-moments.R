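test_that("a Poisson channel has only a first factorial cumulant", {
  K <- matrix(0, 5, 1)
  K[2, 1] <- 2                       # (K)_1 = lambda = 2
  M <- convert_moments(K, "factorial_cumulant", "raw")
  # Poisson(2) raw moments: 1, 2, 6, 22, 94
  expect_equal(M[, 1], c(1, 2, 6, 22, 94))
  # and the inverse direction recovers a pure first factorial cumulant
  back <- convert_moments(M, "raw", "factorial_cumulant")
  expect_equal(back[, 1], c(0, 2, 0, 0, 0), tolerance = 1e-12)
})

test_that("conversions agree with brute-force definitions on a toy PMF", {
  p <- toy_pmf()
  raw <- raw_moments_direct(p, 3, 3)
  expect_equal(convert_moments(fac_moments_direct(p, 3, 3),
                               "factorial_moment", "raw"), raw,
               tolerance = 1e-12)
  # cumulants via numerical differentiation of the log generating function;
  # finite differences are reliable up to total order 4
  low <- outer(0:3, 0:3, "+") <= 4
  K <- convert_moments(raw, "raw", "cumulant")
  Knum <- cumulants_numderiv(p, 3, 3, factorial = FALSE)
  expect_equal(K[1:4, 1:4][low], Knum[low], tolerance = 1e-5)
  # factorial cumulants via the probability generating function
  fK <- convert_moments(raw, "raw", "factorial_cumulant")
  fKnum <- cumulants_numderiv(p, 3, 3, factorial = TRUE)
  expect_equal(fK[1:4, 1:4][low], fKnum[low], tolerance = 1e-5)
})

test_that("conversion chains are closed on random PMFs", {
  set.seed(42)
  kinds <- c("raw", "factorial_moment", "cumulant", "factorial_cumulant")
  for (i in 1:100) {
    p <- matrix(rexp(25), 5, 5)
    p <- p / sum(p)
    raw <- raw_moments_direct(p, 4, 4)
    for (k in kinds[-1]) {
      there <- convert_moments(raw, "raw", k)
      back <- convert_moments(there, k, "raw")
      expect_equal(back, raw, tolerance = 1e-10)
    }
  }
})

test_that("first-order delta-method variance is the variance of the mean", {
  p <- toy_pmf()
  raw <- raw_moments_direct(p, 2, 0)
  v <- mom_variance(raw, 1, 0, N_d = 1000)
  expect_equal(v, (raw[3, 1] - raw[2, 1]^2) / 1000, tolerance = 1e-12)
  # exact 1/N_d scaling
  expect_equal(mom_variance(raw, 1, 0, 10) / mom_variance(raw, 1, 0, 1000), 100)
  expect_error(mom_variance(raw, 2, 0, 100), "2p, 2r")
})

test_that("delta-method variances calibrate against replicate sampling", {
  set.seed(7)
  opt <- opt_eq()
  pmf <- pN_fft(dim_model(N = 1, eps = 0.8), 5e-5, 1e-5)
  n_rep <- 60; n_draw <- 4000
  reps <- replicate(n_rep, {
    xy <- sample_joint_pmf(pmf, n_draw)
    raw <- raw_moments_direct(.pairs_pmf(xy), 2, 2)
    convert_moments(raw, "raw", "factorial_cumulant")[3, 3]
  })
  raw_full <- pmf_moments(pmf, 4, 4)
  v_pred <- mom_variance(raw_full, 2, 2, n_draw)
  ratio <- var(reps) / v_pred
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("variance grows with cumulant order on homogeneous data", {
  pmf <- pN_fft(dim_model(N = 2, eps = 0.4), 5e-5, 1e-5)
  raw <- pmf_moments(pmf, 8, 8)
  v <- vapply(1:4, function(k) mom_variance(raw, k, 0, 1e6), 0)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0))
})

test_that("FCS curves from model cumulants reduce to the classical form", {
  opt <- opt_eq(r = 0.2, s = 3)
  tau_d <- 80e-6
  m <- dim_model(N = 4, eps = 0.3, tau_d = tau_d, opt = opt, T_ref = 1e-9)
  taus <- 10^seq(-6, -2, length.out = 9)
  tab <- model_cumulant_table(m, taus, 1e-9)
  G <- fcs_from_cpch(tab)
  want <- 1 + (2^-1.5 / 4) * (1 + taus / tau_d)^-1 *
    (1 + taus / (9 * tau_d))^-0.5
  expect_equal(G$G, want, tolerance = 1e-12)
  # G -> 1 at large lags
  far <- fcs_from_cpch(model_cumulant_table(m, 10, 1e-9))
  expect_equal(far$G, 1, tolerance = 1e-4)
})

test_that("the zero-lag FCS point uses one-dimensional statistics", {
  # diagonal data: M11(0) = K1 + K1^2 + K2 of the 1D distribution
  tab <- cumulant_table(data.frame(m = c(1, 2), n = c(0, 0), tau = 0,
                                   T = 1e-5, value = c(0.5, 0.02),
                                   variance = NA, N_d = NA))
  G0 <- fcs_from_cpch(tab)
  expect_equal(G0$G, (0.5 + 0.25 + 0.02) / 0.25)
})

test_that("FCA cumulants equal the (n, 0) factorial cumulants", {
  m <- dim_model(N = 3, eps = 0.4, tau_d = 50e-6)
  got <- fca_cumulants(m, n = 1:4, T = 1e-5)
  expect_equal(got$value, factorial_cumulant(1:4, 0, 0, 1e-5, m))
  # and subsetting an empirical table keeps only the single-channel orders
  tab <- model_cumulant_table(m, c(1e-5, 2e-5), 1e-5)
  sub <- fca_cumulants(tab)
  expect_true(all(sub$n == 0))
})
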