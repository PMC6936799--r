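test_that("arrival-time binning reproduces the worked example", {
  b <- bin_arrival_times(c(1, 2, 3, 6, 11, 17, 24, 46), T = 10,
                         sampling_time = 1, duration = 46)
  expect_equal(b$bins, c(1, 2, 3, 5))
  expect_equal(b$counts, c(4, 2, 1, 1))
  expect_equal(b$n_bins, 5)
  expect_equal(counts_from_arrivals(b), c(4, 2, 1, 0, 1))
  # an arrival exactly on a bin edge belongs to that bin (ceiling rule);
  # arrival time zero goes to bin 1
  expect_equal(bin_arrival_times(c(0, 10, 20), 10, 1, 30)$bins, c(1, 2))
  expect_equal(bin_arrival_times(c(0, 10, 20), 10, 1, 30)$counts, c(2, 1))
  expect_error(bin_arrival_times(c(-1, 2), 10), "negative")
  # empty trace
  e <- bin_arrival_times(numeric(0), 10, 1, 100)
  expect_equal(length(e$bins), 0)
  expect_equal(e$n_bins, 10)
})

test_that("the cPCH histogram of the worked example pairs bins correctly", {
  x <- c(4, 2, 1, 0, 1)
  h <- build_cpch_hist(x, tau_k = 1)
  expect_equal(h$total_pairs, 4)
  # pairs are (4,2), (2,1), (1,0), (0,1)
  expect_equal(h$counts[5, 3], 1)   # (4, 2)
  expect_equal(h$counts[3, 2], 1)   # (2, 1)
  expect_equal(h$counts[2, 1], 1)   # (1, 0)
  expect_equal(h$counts[1, 2], 1)   # (0, 1)
  expect_equal(sum(h$counts), h$total_pairs)
})

test_that("sparse and dense histogram routes agree on random traces", {
  set.seed(3)
  for (rep in 1:5) {
    n_ph <- 300
    t_s <- sort(sample.int(5000, n_ph, replace = TRUE))
    T_s <- sample(c(5, 10, 25), 1)
    b <- bin_arrival_times(t_s, T_s, sampling_time = 1, duration = 5000)
    x <- counts_from_arrivals(b)
    for (tk in c(0L, 1L, 7L)) {
      hd <- build_cpch_hist(x, tk)
      hs <- build_cpch_hist(b, tk, method = "sparse")
      a <- max(nrow(hd$counts), nrow(hs$counts))
      bb <- max(ncol(hd$counts), ncol(hs$counts))
      pad <- function(h) {
        m <- matrix(0, a, bb)
        m[1:nrow(h$counts), 1:ncol(h$counts)] <- h$counts
        m
      }
      expect_equal(pad(hd), pad(hs))
      expect_equal(hs$total_pairs, hd$total_pairs)
    }
  }
})

test_that("zero-lag single-channel histograms are diagonal", {
  set.seed(1)
  x <- rpois(500, 1.2)
  h <- build_cpch_hist(x, 0L)
  off <- h$counts; diag(off) <- 0
  expect_equal(sum(off), 0)
  expect_equal(h$total_pairs, 500)
})

test_that("empirical moments follow the histogram definition", {
  h <- build_cpch_hist(c(0, 0, 0, 0), 1L)
  expect_equal(empirical_moments(h, 2, 2), rbind(c(1, 0, 0), 0, 0))
  set.seed(2)
  x <- rpois(2000, 0.7)
  h <- build_cpch_hist(x, 2L)
  M <- empirical_moments(h, 1, 1)
  expect_equal(M[2, 1], mean(x[1:1998]))
  # moments from the histogram equal moments streamed from the counts
  tab <- empirical_cumulants(x, 1e-5, 2L, variances = FALSE)
  raw <- convert_moments(empirical_moments(h, 4, 4), "raw", "factorial_cumulant")
  expect_equal(tab$value, raw[cbind(tab$m + 1, tab$n + 1)], tolerance = 1e-10)
})

test_that("the PCH marginal of an empirical histogram is lag-independent", {
  set.seed(4)
  x <- rpois(20000, 0.9) + rbinom(20000, 1, 0.2)
  margs <- lapply(c(1L, 5L, 40L), function(tk) {
    h <- build_cpch_hist(x, tk)
    rowSums(h$counts) / h$total_pairs
  })
  for (i in 2:3) {
    L <- min(length(margs[[1]]), length(margs[[i]]))
    expect_lt(max(abs(margs[[1]][1:L] - margs[[i]][1:L])), 0.01)
  }
})

test_that("moments of histograms sampled from a model PMF match the model", {
  set.seed(11)
  m <- dim_model(N = 1.5, eps = 0.6)
  pmf <- pN_fft(m, 3e-5, 1e-5)
  xy <- sample_joint_pmf(pmf, 50000)
  emp <- raw_moments_direct(.pairs_pmf(xy), 2, 2)
  K <- convert_moments(emp, "raw", "factorial_cumulant")
  for (mn in list(c(1, 0), c(1, 1), c(2, 1))) {
    want <- factorial_cumulant(mn[1], mn[2], 3e-5, 1e-5, m)
    v <- mom_variance(raw_moments_direct(.pairs_pmf(xy), 2 * mn[1], 2 * mn[2]),
                      mn[1], mn[2], 50000)
    expect_lt(abs(K[mn[1] + 1, mn[2] + 1] - want), 4 * sqrt(v) + 1e-8)
  }
})

test_that("the distribution fit energy is zero for a perfect model and grows under misfit", {
  set.seed(5)
  m <- dim_model(N = 2, eps = 0.5)
  pmf <- pN_fft(m, 2e-5, 1e-5)
  xy <- sample_joint_pmf(pmf, 30000)
  h <- build_cpch_hist(c(xy[, 1]), 0L)  # placeholder shape
  h$counts <- .pairs_pmf(xy) * 30000
  h$total_pairs <- 30000
  emp_pmf <- joint_pmf(h$counts / 30000, 2e-5, 1e-5)
  expect_equal(as.numeric(energy_Ep(list(emp_pmf), list(h))), 0)
  e_true <- energy_Ep(list(pmf), list(h))
  expect_lt(e_true, 3)
  m2 <- dim_model(N = 4, eps = 0.5)   # doubled occupancy
  e_wrong <- energy_Ep(list(pN_fft(m2, 2e-5, 1e-5)), list(h))
  expect_gt(e_wrong, 10 * e_true)
})

test_that("the cumulant fit energy is zero for a perfect model and excludes zero variances", {
  m <- dim_model(N = 2, eps = 0.5)
  tab <- model_cumulant_table(m, c(1e-5, 2e-5), 1e-5)
  emp <- tab
  emp$variance <- 1e-6
  expect_equal(as.numeric(energy_EK(tab, emp)), 0)
  emp$variance[1] <- 0
  expect_warning(e <- energy_EK(tab, emp), "zero")
  expect_equal(attr(e, "n_terms"), nrow(tab) - 1)
})

test_that("multi-tau lag grids are geometric with dense early lags", {
  ks <- multitau_lags(64)
  expect_equal(ks[1:4], 1:4)
  expect_true(all(diff(ks) > 0))
  expect_lte(max(ks), 64)
  expect_true(all(diff(ks)[8:length(diff(ks))] >= 4))
})

test_that("rebinned traces preserve total counts", {
  x <- c(1, 2, 0, 3, 4, 0, 1, 1, 5)
  expect_equal(rebin_counts(x, 2), c(3, 3, 4, 2))
  expect_equal(sum(rebin_counts(x, 3)), sum(x))
})
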