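#' Bin photon arrival times
#'
#' Converts a list of photon arrival times into per-bin photon counts on a
#' bin grid of width `T`. Arrival times and `T` are first expressed as
#' integer multiples of the detector sampling time; the bin index of an
#' arrival at integer time `t_s` is `ceiling(t_s / T_s)` (an arrival at
#' exactly `k * T` falls in bin `k`; an arrival at time 0 is assigned to
#' bin 1).
#'
#' @param t Arrival times, seconds (non-decreasing, non-negative).
#' @param T Bin time, seconds; must be an integer multiple of
#'   `sampling_time`.
#' @param sampling_time Detector clock period, seconds.
#' @param duration Trace duration, seconds; defaults to the last arrival.
#' @return List with `bins` (sorted indices of bins holding photons),
#'   `counts` (photons per such bin) and `n_bins = ceiling(duration / T)`.
#' @examples
#' bin_arrival_times(c(1, 2, 3, 6, 11, 17, 24, 46), T = 10, sampling_time = 1)
#' @export
bin_arrival_times <- function(t, T, sampling_time = 1, duration = NULL) {
  if (any(t < 0)) .stopf("negative arrival times")
  if (is.unsorted(t)) .stopf("arrival times must be non-decreasing")
  T_s <- T / sampling_time
  if (abs(T_s - round(T_s)) > 1e-9)
    .stopf("T must be an integer multiple of the sampling time")
  T_s <- round(T_s)
  t_s <- round(t / sampling_time)
  if (is.null(duration)) duration <- if (length(t)) max(t) else T
  n_bins <- as.integer(ceiling(round(duration / sampling_time) / T_s))
  if (!length(t))
    return(list(bins = integer(0), counts = integer(0), n_bins = n_bins))
  b <- pmax(1L, as.integer(ceiling(t_s / T_s)))
  r <- rle(b)
  list(bins = r$values, counts = r$lengths, n_bins = max(n_bins, max(b)))
}

#' Dense count trace from binned arrivals
#'
#' @param binned Result of [bin_arrival_times()].
#' @return Integer vector of counts per bin.
#' @export
counts_from_arrivals <- function(binned) {
  x <- integer(binned$n_bins)
  x[binned$bins] <- binned$counts
  x
}

#' Empirical cPCH histogram
#'
#' Tallies pairs of photon counts in bins separated by `tau_k` bin widths
#' into a two-dimensional histogram. Only pairs fully inside the trace are
#' used (no wraparound), so the number of pairs is `n_bins - tau_k`. With a
#' single channel at `tau_k = 0` every bin is paired with itself and all
#' mass lies on the diagonal.
#'
#' Two equivalent routes are provided: `"dense"` tabulates the shifted
#' count vectors directly; `"sparse"` follows the arrival-time bookkeeping
#' (intersection of the positive-count bin lists for the (+,+) cells, set
#' differences for the (+,0) and (0,+) edges, and pair accounting for the
#' (0,0) cell), which is efficient for dim traces at small bin times.
#'
#' @param x Counts per bin, first channel (integer vector), or the output
#'   of [bin_arrival_times()] for the sparse route.
#' @param tau_k Lag in units of the bin time (non-negative integer).
#' @param y Second channel counts (defaults to `x`).
#' @param tau,T Optional lag/bin time in seconds, stored as metadata.
#' @param method `"dense"` or `"sparse"`.
#' @return Object of class `cpch_hist`: matrix `counts` over count pairs
#'   `0..max`, `total_pairs`, and metadata.
#' @export
build_cpch_hist <- function(x, tau_k, y = NULL, tau = NA_real_, T = NA_real_,
                            method = c("dense", "sparse")) {
  method <- match.arg(method)
  if (tau_k < 0 || tau_k != round(tau_k)) .stopf("tau_k must be a non-negative integer")
  tau_k <- as.integer(tau_k)
  if (method == "sparse") {
    if (!is.list(x)) .stopf("sparse route requires bin_arrival_times() input")
    return(.cpch_hist_sparse(x, tau_k, if (is.null(y)) x else y, tau, T))
  }
  x <- as.integer(x)
  y <- if (is.null(y)) x else as.integer(y)
  n <- min(length(x), length(y))
  if (tau_k >= n) .stopf("lag tau_k = %d leaves no bin pairs", tau_k)
  na <- x[1:(n - tau_k)]
  nb <- y[(1 + tau_k):n]
  A <- max(na); B <- max(nb)
  idx <- na * (B + 1L) + nb + 1L
  h <- tabulate(idx, nbins = (A + 1L) * (B + 1L))
  counts <- matrix(h, nrow = A + 1L, ncol = B + 1L, byrow = TRUE)
  structure(list(counts = counts, total_pairs = n - tau_k, tau_k = tau_k,
                 tau = tau, T = T), class = "cpch_hist")
}

.cpch_hist_sparse <- function(bx, tau_k, by, tau, T) {
  n <- min(bx$n_bins, by$n_bins)
  if (tau_k >= n) .stopf("lag tau_k = %d leaves no bin pairs", tau_k)
  total <- n - tau_k
  # start bins i in 1..total pair (i, i + tau_k)
  ia <- bx$bins[bx$bins <= total]
  ca <- bx$counts[bx$bins <= total]
  ib <- by$bins[by$bins > tau_k & by$bins <= n] - tau_k
  cb <- by$counts[by$bins > tau_k & by$bins <= n]
  A <- if (length(ca)) max(ca) else 0L
  B <- if (length(cb)) max(cb) else 0L
  counts <- matrix(0L, A + 1L, B + 1L)
  m <- match(ia, ib)
  both <- !is.na(m)
  # (+,+): bins present in both lists
  if (any(both)) {
    tab <- table(factor(ca[both], levels = 0:A), factor(cb[m[both]], levels = 0:B))
    counts <- counts + unclass(tab)
  }
  # (+,0): in first list only
  if (any(!both)) {
    ta <- tabulate(ca[!both], nbins = A)
    counts[-1, 1] <- counts[-1, 1] + ta
  }
  # (0,+): in second list only
  onlyb <- is.na(match(ib, ia))
  if (any(onlyb)) {
    tb <- tabulate(cb[onlyb], nbins = B)
    counts[1, -1] <- counts[1, -1] + tb
  }
  counts[1, 1] <- total - sum(counts)
  structure(list(counts = counts, total_pairs = total, tau_k = tau_k,
                 tau = tau, T = T), class = "cpch_hist")
}

#' @export
print.cpch_hist <- function(x, ...) {
  cat(sprintf("cpch_hist: %d x %d cells, %d pairs, tau_k=%d\n",
              nrow(x$counts), ncol(x$counts), x$total_pairs, x$tau_k))
  invisible(x)
}

#' Normalise a cPCH histogram to an empirical probability distribution
#'
#' @param hist A `cpch_hist`.
#' @return A `joint_pmf` whose values sum to 1.
#' @export
normalize_hist <- function(hist) {
  stopifnot(inherits(hist, "cpch_hist"))
  joint_pmf(hist$counts / hist$total_pairs, hist$tau, hist$T, "empirical")
}

#' Empirical raw moments
#'
#' Raw bivariate moments `M_{m,n} = sum n_x^m n_y^n p_em(n_x, n_y)` of an
#' empirical histogram, by direct summation.
#'
#' @param hist A `cpch_hist`.
#' @param max_m,max_n Maximum orders.
#' @return Matrix of raw moments indexed `[m + 1, n + 1]`.
#' @export
empirical_moments <- function(hist, max_m = 4, max_n = 4) {
  stopifnot(inherits(hist, "cpch_hist"))
  pmf_moments(hist$counts / hist$total_pairs, max_m, max_n)
}

#' Empirical factorial cumulants over a lag grid
#'
#' The workhorse of cumulant fitting: streams a binned count trace once per
#' lag, accumulating the raw bivariate moments of all lagged count pairs
#' (to the orders needed for both the cumulants and their delta-method
#' variances), converts them to factorial cumulants, and attaches
#' moments-of-moments variances.
#'
#' @param x Counts per bin, first channel.
#' @param T Bin time, s.
#' @param tau_k Integer lags (in bins).
#' @param y Second channel (defaults to `x`: single-channel cPCH).
#' @param orders Two-column matrix of (m, n) orders; default all
#'   `1 <= m + n <= 4`.
#' @param variances Attach moments-of-moments variances (default TRUE).
#' @param acf_correction Inflate the variances of the pure-channel orders
#'   (`m = 0` or `n = 0`) by an autocorrelation factor estimated from the
#'   trace (default TRUE). The moments-of-moments covariance treats bin
#'   pairs as independent, which is adequate for the joint orders but
#'   underestimates the sampling variance of single-channel cumulants,
#'   whose constituent moments are means of strongly autocorrelated series.
#'   The factor is `1 + 2 * sum_k rho_k` for the series `x_t^m`, with the
#'   autocorrelation summed by trapezoid over the computed lag grid.
#' @param marginals_once Keep the pure-channel orders only at the first lag
#'   (they are lag-independent, so one entry carries all the information);
#'   default FALSE.
#' @param segments When an integer `k >= 3`, split the trace into `k`
#'   contiguous segments (each far longer than any correlation time),
#'   estimate every cumulant per segment, and report the across-segment
#'   mean with the across-segment variance of the mean. This replicate
#'   estimate is honestly calibrated for all orders, including the
#'   autocorrelation effects that the delta-method treatment (which assumes
#'   independent bin pairs) can only approximate.
#' @return A `cumulant_table` (kind `factorial_cumulant`).
#' @export
empirical_cumulants <- function(x, T, tau_k, y = NULL,
                                orders = default_orders(), variances = TRUE,
                                acf_correction = TRUE,
                                marginals_once = FALSE, segments = NULL) {
  if (!is.null(segments) && variances) {
    segments <- as.integer(segments)
    if (segments < 3) .stopf("need at least 3 segments")
    n <- if (is.null(y)) length(x) else min(length(x), length(y))
    if (n / segments <= 4 * max(tau_k))
      .stopf("segments too short for the requested lags")
    brk <- floor(seq(0, n, length.out = segments + 1))
    tabs <- lapply(seq_len(segments), function(i) {
      idx <- (brk[i] + 1):brk[i + 1]
      empirical_cumulants(x[idx], T, tau_k, y = if (is.null(y)) NULL else y[idx],
                          orders = orders, variances = FALSE,
                          marginals_once = marginals_once)
    })
    vals <- vapply(tabs, function(t) t$value, tabs[[1]]$value)
    out <- tabs[[1]]
    out$value <- rowMeans(vals)
    out$variance <- apply(vals, 1, stats::var) / segments
    out$N_d <- out$N_d * segments  # total pairs across segments
    return(out)
  }
  x <- as.numeric(x)
  two_channel <- !is.null(y)
  y <- if (is.null(y)) x else as.numeric(y)
  orders <- as.matrix(orders)
  tau_k <- as.integer(tau_k)
  pmax_ <- max(orders[, 1]); rmax_ <- max(orders[, 2])
  max_m <- if (variances) 2L * pmax_ else pmax_
  max_n <- if (variances) 2L * rmax_ else rmax_
  mask <- matrix(FALSE, max_m + 1, max_n + 1)
  for (i in seq_len(nrow(orders))) {
    p <- orders[i, 1]; r <- orders[i, 2]
    a <- if (variances) 2 * p else p
    b <- if (variances) 2 * r else r
    mask[1:(a + 1), 1:(b + 1)] <- TRUE
  }
  raws <- .lagged_moments_cpp(x, y, tau_k, max_m, max_n, mask)
  infl_A <- infl_B <- rep(1, max(pmax_, rmax_))
  if (variances && acf_correction) {
    infl_A <- .acf_inflation(x, x, tau_k, raws, pmax_, two_channel)
    infl_B <- if (two_channel)
      .acf_inflation(y, y, tau_k, NULL, rmax_, TRUE) else infl_A
  }
  rows <- vector("list", length(tau_k))
  for (t in seq_along(tau_k)) {
    raw <- raws[[t]]
    N_d <- length(x) - tau_k[t]
    sub <- raw[1:(pmax_ + 1), 1:(rmax_ + 1), drop = FALSE]
    sub[is.na(sub)] <- 0
    K <- convert_moments(sub, "raw", "factorial_cumulant")
    keep <- rep(TRUE, nrow(orders))
    if (marginals_once && t > 1)
      keep <- orders[, 1] >= 1 & orders[, 2] >= 1
    v <- rep(NA_real_, nrow(orders))
    if (variances)
      v <- vapply(seq_len(nrow(orders)), function(i) {
        if (!keep[i]) return(NA_real_)
        vv <- mom_variance(raw[1:(2 * orders[i, 1] + 1),
                               1:(2 * orders[i, 2] + 1), drop = FALSE],
                           orders[i, 1], orders[i, 2], N_d)
        if (orders[i, 2] == 0) vv <- vv * infl_A[orders[i, 1]]
        else if (orders[i, 1] == 0) vv <- vv * infl_B[orders[i, 2]]
        vv
      }, 0)
    rows[[t]] <- data.frame(m = orders[keep, 1], n = orders[keep, 2],
                            tau = tau_k[t] * T, T = T,
                            value = K[cbind(orders[keep, 1] + 1,
                                            orders[keep, 2] + 1)],
                            variance = v[keep], N_d = N_d)
  }
  cumulant_table(do.call(rbind, rows))
}

# variance inflation 1 + 2*sum_k rho_k for the series x^m, m = 1..pmax;
# reuses the already-computed lagged raw moments when the two channels are
# the same trace, otherwise computes the needed diagonal moments
.acf_inflation <- function(x, y, tau_k, raws, pmax_, recompute) {
  if (pmax_ < 1) return(numeric(0))
  if (!recompute && !is.null(raws)) {
    # the reused moment matrices must hold the (m, m) diagonal entries
    ok <- nrow(raws[[1]]) > pmax_ && ncol(raws[[1]]) > pmax_ &&
      !anyNA(diag(raws[[1]])[seq_len(pmax_ + 1)])
    if (!ok) recompute <- TRUE
  }
  if (recompute || is.null(raws)) {
    mask <- matrix(FALSE, 2 * pmax_ + 1, 2 * pmax_ + 1)
    for (m in 1:pmax_) {
      mask[m + 1, m + 1] <- TRUE
      mask[2 * m + 1, 1] <- TRUE
      mask[m + 1, 1] <- TRUE
      mask[1, m + 1] <- TRUE
    }
    raws <- .lagged_moments_cpp(x, y, as.integer(tau_k), 2L * pmax_,
                                2L * pmax_, mask)
  }
  ks <- as.numeric(tau_k)
  vapply(1:pmax_, function(m) {
    mu <- raws[[1]][m + 1, 1]
    v0 <- raws[[1]][2 * m + 1, 1] - mu^2
    if (!is.finite(v0) || v0 <= 0) return(1)
    rho <- vapply(seq_along(ks), function(t)
      (raws[[t]][m + 1, m + 1] - mu * raws[[t]][1, m + 1]) / v0, 0)
    rho <- pmax(pmin(rho, 1), 0)
    # trapezoid over the (generally geometric) integer lag grid, with the
    # segment from lag 0 to the first computed lag counted as rho_1
    s <- rho[1] * (ks[1] - 0)
    if (length(ks) > 1)
      s <- s + sum(0.5 * (rho[-1] + rho[-length(ks)]) * diff(ks))
    1 + 2 * s
  }, 0)
}

#' Multi-tau lag grid
#'
#' Integer lags 1..4 followed by geometrically growing spacing (doubling
#' every `per_octave` lags), the standard multi-tau correlator layout.
#'
#' @param max_k Largest lag, in bins.
#' @param per_octave Lags per doubling (default 4).
#' @return Increasing integer vector of lags.
#' @export
multitau_lags <- function(max_k, per_octave = 4) {
  ks <- seq_len(min(per_octave, max_k))
  inc <- 2
  last <- ks[length(ks)]
  while (last < max_k) {
    for (i in seq_len(per_octave)) {
      last <- last + inc
      if (last > max_k) break
      ks <- c(ks, last)
    }
    inc <- inc * 2
  }
  ks
}

#' Multi-tau factorial cumulants with growing bin times
#'
#' Computes empirical factorial cumulants on the multi-tau correlator
#' layout: the first octave uses the native bin time `dt` with lags
#' `1..8` (in bins); every further octave doubles the bin time (rebinned
#' trace) and uses lags `5..8` in units of the new bin, so that the lag
#' grid is geometric while the counting bin grows alongside the lag. The
#' growing bins trade time resolution for counts per bin, which the model
#' side compensates with the binning functions.
#'
#' @param x Counts per bin at the native bin time.
#' @param dt Native bin time, s.
#' @param n_octaves Number of doublings beyond the first octave.
#' @param y Second channel (defaults to `x`).
#' @param base_lags Integer lags used at the native bin time (default
#'   `1:8`); pass a longer multi-tau grid to combine a full fixed-`T` lag
#'   scan with the growing-bin octaves.
#' @param segments Passed to [empirical_cumulants()]; segment-replicate
#'   variances (the default) are recommended for fitting.
#' @param orders,variances As in [empirical_cumulants()].
#' @return A `cumulant_table` spanning all (tau, T) pairs.
#' @export
multitau_cumulants <- function(x, dt, n_octaves = 6, y = NULL,
                               base_lags = 1:8, segments = 10,
                               orders = default_orders(), variances = TRUE) {
  if (is.null(y)) y <- x
  out <- list(empirical_cumulants(x, dt, base_lags, y = y, orders = orders,
                                  variances = variances,
                                  marginals_once = TRUE, segments = segments))
  T <- dt
  for (j in seq_len(n_octaves)) {
    x <- rebin_counts(x, 2)
    y <- rebin_counts(y, 2)
    T <- 2 * T
    if (length(x) <= 16 * max(1, segments)) break
    out[[j + 1]] <- empirical_cumulants(x, T, 5:8, y = y, orders = orders,
                                        variances = variances,
                                        marginals_once = TRUE,
                                        segments = segments)
  }
  res <- do.call(rbind, out)
  structure(res, class = c("cumulant_table", "data.frame"),
            kind = "factorial_cumulant")
}

#' Rebin a count trace to a larger bin time
#'
#' @param x Counts per bin.
#' @param factor Integer number of bins to merge.
#' @return Shorter counts vector (any remainder bins are dropped).
#' @export
rebin_counts <- function(x, factor) {
  factor <- as.integer(factor)
  n <- (length(x) %/% factor) * factor
  colSums(matrix(x[1:n], nrow = factor))
}

#' Distribution fit energy
#'
#' Mean squared deviation between model and empirical cPCH distributions,
#' normalised per cell by the binomial sampling variance
#' `sigma_p^2 = p_em (1 - p_em) / N_d` and averaged over all histogram
#' cells and lags. Close to 1 when the model describes the data within
#' sampling error. Cells where `sigma_p = 0` (empirical probability 0 or 1)
#' are excluded; their number is returned as an attribute.
#'
#' @param model_pmfs List of `joint_pmf`s, one per lag.
#' @param emp_hists List of `cpch_hist`s on the same lag grid.
#' @return Energy value, with attributes `n_cells` and `n_excluded`.
#' @export
energy_Ep <- function(model_pmfs, emp_hists) {
  if (length(model_pmfs) != length(emp_hists)) .stopf("lag grids do not match")
  num <- 0; L <- 0; excl <- 0
  for (i in seq_along(model_pmfs)) {
    mp <- model_pmfs[[i]]$values
    h <- emp_hists[[i]]
    N_d <- h$total_pairs
    pe <- h$counts / N_d
    a <- min(nrow(mp), nrow(pe)); b <- min(ncol(mp), ncol(pe))
    pm <- mp[1:a, 1:b]; pe <- pe[1:a, 1:b]
    s2 <- pe * (1 - pe) / N_d
    ok <- s2 > 0
    excl <- excl + sum(!ok)
    num <- num + sum((pm[ok] - pe[ok])^2 / s2[ok])
    L <- L + sum(ok)
  }
  structure(num / L, n_cells = L, n_excluded = excl)
}

#' Factorial-cumulant fit energy
#'
#' Sum of squared differences between model and empirical factorial
#' cumulants, each normalised by the moments-of-moments variance of the
#' empirical value, divided by the total number of moments used. Close to 1
#' for a correct model.
#'
#' @param model_tab,emp_tab `cumulant_table`s on matching (m, n, tau) grids
#'   (`emp_tab` must carry variances).
#' @return Energy value with attribute `n_terms`.
#' @export
energy_EK <- function(model_tab, emp_tab) {
  key <- function(d) paste(d$m, d$n, signif(d$tau, 12), signif(d$T, 12),
                           sep = "|")
  i <- match(key(emp_tab), key(model_tab))
  if (anyNA(i)) .stopf("model table lacks %d empirical entries", sum(is.na(i)))
  v <- emp_tab$variance
  ok <- is.finite(v) & v > 0
  if (!all(ok)) .warnf("excluding %d cumulants with zero/missing variance", sum(!ok))
  d2 <- (model_tab$value[i][ok] - emp_tab$value[ok])^2 / v[ok]
  structure(sum(d2) / sum(ok), n_terms = sum(ok))
}
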