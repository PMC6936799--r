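test_that("identical seeds give identical traces; different seeds differ", {
  m <- dim_model(N = 0.5, eps = 0.8, tau_d = 50e-6)
  a <- simulate_trace(m, 0.2, 1e-5, seed = 42)
  b <- simulate_trace(m, 0.2, 1e-5, seed = 42)
  d <- simulate_trace(m, 0.2, 1e-5, seed = 43)
  expect_identical(a$A, b$A)
  expect_false(identical(a$A, d$A))
})

test_that("mean counts per bin match the first factorial cumulant within 3 sigma", {
  m <- dim_model(N = 1, eps = 0.6, tau_d = 50e-6, lambda_A = 0.1)
  tr <- simulate_trace(m, 3, 1e-5, seed = 8)
  mu <- factorial_cumulant(1, 0, 0, 1e-5, m)
  # conservative error: variance of the mean of correlated counts
  tab <- empirical_cumulants(tr$A, 1e-5, 1L)
  se <- sqrt(tab$variance[tab$m == 1 & tab$n == 0])
  expect_lt(abs(mean(tr$A) - mu), 3 * se + 3 * mu * 0.02)
})

test_that("immobile molecules give Poisson counts (unit index of dispersion)", {
  # with D = 0 the configuration is frozen and the counts in each bin are
  # conditionally Poisson with a constant mean
  m <- cpch_model(opt_eq(), species_params(2, 0.5 / 1e-5, D = 0), T_ref = 1e-5)
  tr <- simulate_trace(m, 2, 1e-5, seed = 5)
  x <- tr$A
  iod <- var(x) / mean(x)
  # dispersion index of a Poisson sample: 1 +/- sqrt(2/n)
  expect_lt(abs(iod - 1), 5 * sqrt(2 / length(x)))
  # and the counts are uncorrelated in time
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 5 / sqrt(length(x)))
})

test_that("occupancy stays stationary along the trace", {
  m <- dim_model(N = 2, eps = 0.5, tau_d = 50e-6)
  tr <- simulate_trace(m, 3, 1e-5, seed = 13)
  thirds <- split(tr$A, rep(1:3, each = length(tr$A) / 3))
  mus <- vapply(thirds, mean, 0)
  tab <- empirical_cumulants(tr$A, 1e-5, 1L)
  se <- sqrt(3 * tab$variance[tab$m == 1 & tab$n == 0])
  expect_lt(max(mus) - min(mus), 8 * se)
})

test_that("empirical FCS and joint cumulants of a trace match theory within errors", {
  m <- dim_model(N = 1, eps = 0.8, tau_d = 50e-6)
  tr <- simulate_trace(m, 4, 1e-5, seed = 21)
  lags <- c(1L, 2L, 4L, 8L, 16L, 32L)
  tab <- empirical_cumulants(tr$A, 1e-5, lags)
  mod <- tab
  mod$value <- factorial_cumulant(tab$m, tab$n, tab$tau, tab$T, m)
  joint <- tab$m >= 1 & tab$n >= 1
  z <- (tab$value[joint] - mod$value[joint]) / sqrt(tab$variance[joint])
  expect_lt(mean(z^2), 3)
  expect_lt(max(abs(z)), 5)
  # FCS curve from the same cumulants tracks the closed form
  G <- fcs_from_cpch(tab)
  want <- fcs_from_cpch(mod)
  expect_lt(max(abs(G$G - want$G) / sqrt(G$var_G)), 5)
})

test_that("dual-channel emission obeys the per-channel brightness", {
  opt <- opt_eq()
  m <- cpch_model(opt, species_params(1, 0.6 / 1e-5, 0.3 / 1e-5, tau_d = 5e-5),
                  T_ref = 1e-5)
  tr <- simulate_trace(m, 2, 1e-5, seed = 3)
  expect_equal(mean(tr$B) / mean(tr$A), 0.5, tolerance = 0.15)
  # zero-lag cross-correlation is positive (same molecules in both channels)
  tabx <- empirical_cumulants(tr$A, 1e-5, 1L, y = tr$B)
  k11 <- tabx$value[tabx$m == 1 & tabx$n == 1]
  expect_gt(k11, 0)
})

test_that("image stacks reproduce the per-pixel mean and frame reproducibility", {
  p <- cpch_preset("table2_spatial")
  g <- scan_geometry(0.0117, dwell = 1e-5, line_retrace = 1e-3,
                     frame_retrace = 5e-3, pixels_per_line = 64)
  st <- simulate_image_stack(p$model, g, frames = 3, seed = 2)
  expect_equal(dim(st$counts), c(64, 64, 3))
  mu <- factorial_cumulant(1, 0, 0, 1e-5, p$model)
  expect_equal(mean(st$counts), mu, tolerance = 0.25)
  a <- simulate_image_stack(p$model, g, frames = 1, seed = 7)
  b <- simulate_image_stack(p$model, g, frames = 1, seed = 7)
  expect_identical(a$counts, b$counts)
})

test_that("frozen bright molecules leave a static point-spread pattern", {
  g <- scan_geometry(0.05, dwell = 1e-5, line_retrace = 0,
                     pixels_per_line = 32)
  m <- cpch_model(opt_eq(r = 0.25, s = 3),
                  species_params(0.02, 50 / 1e-5, D = 0), T_ref = 1e-5)
  st <- simulate_image_stack(m, g, frames = 4, seed = 10)
  # frames are repeated scans of the same frozen configuration: their
  # pixelwise correlation is high, unlike for a diffusing species
  f1 <- as.vector(st$counts[, , 1]); f2 <- as.vector(st$counts[, , 4])
  expect_gt(cor(f1, f2), 0.5)
  md <- cpch_model(opt_eq(r = 0.25, s = 3),
                   species_params(0.02, 50 / 1e-5, D = 100), T_ref = 1e-5)
  std <- simulate_image_stack(md, g, frames = 4, seed = 10)
  expect_lt(cor(as.vector(std$counts[, , 1]), as.vector(std$counts[, , 4])),
            0.3)
})

test_that("arrival-time conversion preserves bin-level counts", {
  set.seed(30)
  x <- rpois(200, 0.8)
  t <- trace_to_arrivals(x, 1e-5, sampling_time = 50e-9)
  b <- bin_arrival_times(t, 1e-5, sampling_time = 50e-9,
                         duration = 200 * 1e-5)
  expect_equal(counts_from_arrivals(b)[1:200], x)
})

test_that("fixtures are reproducible and round-trip through the config reader", {
  dir <- tempfile()
  f1 <- make_fixture("table1_single", seed = 4, dir = dir, duration = 0.05)
  h1 <- tools::md5sum(unlist(f1))
  f2 <- make_fixture("table1_single", seed = 4, dir = dir, duration = 0.05)
  expect_identical(unname(h1), unname(tools::md5sum(unlist(f2))))
  truth <- jsonlite::read_json(f1$truth, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(truth$model, cfg, auto_unbox = TRUE, digits = NA)
  m <- read_cpch_config(cfg)
  expect_equal(m$species[[1]]$eps_A, 24448)
  expect_equal(m$species[[1]]$D, 0.2651^2 / (4 * 175.7e-6), tolerance = 1e-6)
  # the ligand-receptor preset has three species with doubled brightness
  lr <- cpch_preset("ligand_receptor")
  eps <- vapply(lr$model$species, `[[`, 0, "eps_A")
  expect_equal(eps[3] / eps[1], 2)
  D <- vapply(lr$model$species, `[[`, 0, "D")
  expect_lt(D[2], D[1] / 10)
  expect_error(cpch_preset("nope"), "unknown preset")
})
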