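# Shared small models and numerical oracles used across the tests.

opt_eq <- function(r = 0.25, s = 5) optical_config(r, s * r)
opt_uneq <- function() optical_config(0.25, 1.25, r_B = 0.3, z_B = 1.0)

# a dim single species, brightness given in counts/bin for convenience
dim_species <- function(N = 2, eps = 0.5, tau_d = 50e-6)
  species_params(N, eps, eps_unit = "counts_per_bin", tau_d = tau_d)

dim_model <- function(N = 2, eps = 0.5, tau_d = 50e-6, opt = opt_eq(),
                      lambda_A = 0, lambda_B = 0, T_ref = 1e-5)
  cpch_model(opt, dim_species(N, eps, tau_d), T_ref = T_ref,
             lambda_A = lambda_A, lambda_B = lambda_B)

# quadrature oracle for the shape factor: 3D integral of the normalised
# intensity product over space, divided by the observation volume
# (separable Gaussians integrated per axis)
gamma_quadrature <- function(m, n, opt) {
  gauss_1d <- function(cc) stats::integrate(function(x) exp(-cc * x^2),
                                            -Inf, Inf, rel.tol = 1e-12)$value
  cr <- 2 * (m / opt$r_A^2 + n / opt$r_B^2)
  cz <- 2 * (m / opt$z_A^2 + n / opt$z_B^2)
  gauss_1d(cr)^2 * gauss_1d(cz) / observation_volume(opt)
}

# quadrature oracle for one spatial dimension of the lagged correlation
# integral (Gaussian profile x diffusion propagator), normalised by its
# tau = 0 value; the full kappa is radial^2 * axial
kappa_dim_quadrature <- function(m, n, tau, D, wA, wB, v = 0) {
  a <- 2 * m / wA^2; b <- 2 * n / wB^2; s2 <- 2 * D * tau
  inner <- function(x) vapply(x, function(xx)
    stats::integrate(function(y)
      exp(-b * y^2 - (y - xx - v * tau)^2 / (2 * s2)) / sqrt(2 * pi * s2),
      -Inf, Inf, rel.tol = 1e-11, abs.tol = 0)$value, 0)
  val <- stats::integrate(function(x) exp(-a * x^2) * inner(x),
                          -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  val / sqrt(pi / (a + b))
}

# defining second-order binning integral, by quadrature
B2_quadrature <- function(alpha, beta) {
  f <- function(u) (alpha - u) / ((1 + u) * sqrt(1 + beta * u))
  2 / alpha^2 * stats::integrate(f, 0, alpha, rel.tol = 1e-10)$value
}

# raw moments of a bivariate PMF by direct summation (independent oracle)
raw_moments_direct <- function(p, max_m, max_n) {
  nx <- 0:(nrow(p) - 1); ny <- 0:(ncol(p) - 1)
  out <- matrix(0, max_m + 1, max_n + 1)
  for (m in 0:max_m) for (n in 0:max_n)
    out[m + 1, n + 1] <- sum(outer(nx^m, ny^n) * p)
  out
}

# factorial moments by direct summation of falling factorials
fac_moments_direct <- function(p, max_m, max_n) {
  ff <- function(k, m) if (m == 0) rep(1, length(k)) else
    vapply(k, function(x) prod(x - 0:(m - 1)), 0)
  nx <- 0:(nrow(p) - 1); ny <- 0:(ncol(p) - 1)
  out <- matrix(0, max_m + 1, max_n + 1)
  for (m in 0:max_m) for (n in 0:max_n)
    out[m + 1, n + 1] <- sum(outer(ff(nx, m), ff(ny, n)) * p)
  out
}

# cumulants by high-order central finite differences of the log generating
# function (independent of the package's recursion route)
cumulants_numderiv <- function(p, max_m, max_n, factorial = FALSE, h = 1e-2) {
  nx <- 0:(nrow(p) - 1); ny <- 0:(ncol(p) - 1)
  logg <- function(t, s) {
    if (factorial) log(sum(outer((1 + t)^nx, (1 + s)^ny) * p))
    else log(sum(outer(exp(t * nx), exp(s * ny)) * p))
  }
  # 9-point central difference weights for derivatives up to order 4
  pts <- -4:4
  wts <- list(
    `0` = as.numeric(pts == 0),
    `1` = c(3, -32, 168, -672, 0, 672, -168, 32, -3) / 840,
    `2` = c(-9, 128, -1008, 8064, -14350, 8064, -1008, 128, -9) / 5040,
    `3` = c(-7, 72, -338, 488, 0, -488, 338, -72, 7) / 240,
    `4` = c(7, -96, 676, -1952, 2730, -1952, 676, -96, 7) / 240)
  out <- matrix(0, max_m + 1, max_n + 1)
  for (m in 0:max_m) for (n in 0:max_n) {
    if (m + n == 0) next
    acc <- 0
    for (i in seq_along(pts)) for (j in seq_along(pts)) {
      w <- wts[[m + 1]][i] * wts[[n + 1]][j]
      if (w != 0) acc <- acc + w * logg(pts[i] * h, pts[j] * h)
    }
    out[m + 1, n + 1] <- acc / h^(m + n)
  }
  out
}

# empirical PMF matrix from sampled (n_x, n_y) pairs
.pairs_pmf <- function(xy) {
  A <- max(xy[, 1]); B <- max(xy[, 2])
  tab <- table(factor(xy[, 1], levels = 0:A), factor(xy[, 2], levels = 0:B))
  unclass(tab) / nrow(xy)
}

# a small arbitrary bivariate PMF on 4x4 support
toy_pmf <- function() {
  p <- matrix(c(5, 2, 1, 0.5,
                3, 4, 1, 0.2,
                1, 1, 2, 0.4,
                0.3, 0.2, 0.4, 1), 4, 4, byrow = TRUE)
  p / sum(p)
}
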