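#' Nested-sampling energy minimiser
#'
#' Population Markov-chain Monte Carlo in the nested-sampling style, used
#' as a global optimiser on rugged fit-energy landscapes: a set of live
#' parameter vectors is maintained; at each iteration the worst (highest
#' energy) member is recorded and replaced by a copy of another member,
#' which is then updated one parameter at a time with Gaussian proposals
#' (log-normal for parameters flagged `log_scale`). Proposals inside the
#' bounds are always accepted when the new energy is below `E_min`
#' (exploring everything compatible with the data), otherwise by a
#' unit-temperature Metropolis step. Step sizes adapt per parameter by
#' `exp(1/n_accepted)` (grow when acceptance dominates) or
#' `exp(-1/n_rejected)`.
#'
#' @param energy Function mapping a parameter vector to a scalar energy
#'   (may return `Inf` for forbidden regions, e.g. ordering constraints).
#' @param lower,upper Named numeric bounds (finite).
#' @param log_scale Logical vector: propose multiplicatively (used for
#'   diffusion parameters).
#' @param n_live Number of live points (default 100).
#' @param steps_per_param Update proposals per parameter per replacement.
#' @param max_iter Maximum number of replacements.
#' @param E_min Energy below which all moves are accepted (default 2).
#' @param E_stop Optional early-stop threshold on the worst live energy.
#' @param stagnation Relative change of the live-set mean below which the
#'   run terminates (checked every 100 replacements).
#' @param burn_in Fraction of recorded points discarded before averaging.
#' @param init Optional matrix of initial parameter sets (rows), recycled
#'   or subsampled to `n_live`; remaining points drawn uniformly in the
#'   bounds (log-uniformly for `log_scale` parameters).
#' @param seed Optional seed ([set.seed()]).
#' @return Object of class `cpch_fit`: `estimate` (mean of recorded points
#'   after burn-in), `best` (lowest-energy point seen), `best_energy`,
#'   `recorded` (matrix with energies), `diagnostics`.
#' @export
nested_sampling_fit <- function(energy, lower, upper,
                                log_scale = rep(FALSE, length(lower)),
                                n_live = 100, steps_per_param = 20,
                                max_iter = 500, E_min = 2, E_stop = NULL,
                                stagnation = 1e-4, burn_in = 0.25,
                                init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npar <- length(lower)
  if (length(upper) != npar || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower)) .stopf("invalid bounds")
  pn <- names(lower)
  if (is.null(pn)) pn <- paste0("p", seq_len(npar))

  draw_uniform <- function(k) {
    m <- matrix(0, k, npar)
    for (j in seq_len(npar)) {
      m[, j] <- if (log_scale[j])
        exp(runif(k, log(lower[j]), log(upper[j])))
      else runif(k, lower[j], upper[j])
    }
    m
  }
  live <- draw_uniform(n_live)
  if (!is.null(init)) {
    init <- as.matrix(init)
    ok <- apply(init, 1, function(p) all(p >= lower & p <= upper))
    init <- init[ok, , drop = FALSE]
    k <- min(nrow(init), n_live)
    if (k > 0) live[seq_len(k), ] <- init[sample.int(nrow(init), k), , drop = FALSE]
  }
  colnames(live) <- pn
  E <- apply(live, 1, energy)
  if (all(!is.finite(E))) .stopf("no finite-energy initial parameter set")
  # step sizes per live point and parameter
  span <- ifelse(log_scale, log(upper / lower), upper - lower) / 10
  steps <- matrix(rep(span, each = n_live), n_live, npar)

  recorded <- matrix(NA_real_, max_iter, npar, dimnames = list(NULL, pn))
  rec_E <- rep(NA_real_, max_iter)
  best <- live[which.min(E), ]
  best_E <- min(E)
  prev_mean <- colMeans(live)
  n_done <- 0

  for (it in seq_len(max_iter)) {
    worst <- which.max(E)
    recorded[it, ] <- live[worst, ]
    rec_E[it] <- E[worst]
    # the classic nested-sampling constraint, relaxed by the E_min floor:
    # replacements never exceed the energy of the point they replace
    cap <- max(E_min, E[worst])
    src <- sample(setdiff(seq_len(n_live), worst), 1)
    x <- live[src, ]
    Ex <- E[src]
    st <- steps[src, ]
    for (j in seq_len(npar)) {
      acc <- 0L; rej <- 0L
      for (k in seq_len(steps_per_param)) {
        xp <- x
        xp[j] <- if (log_scale[j]) x[j] * exp(st[j] * rnorm(1))
                 else x[j] + st[j] * rnorm(1)
        if (xp[j] < lower[j] || xp[j] > upper[j]) { rej <- rej + 1L; next }
        Ep <- energy(xp)
        take <- is.finite(Ep) && Ep <= cap &&
          (Ep < E_min || Ep <= Ex || runif(1) < exp(-(Ep - Ex)))
        if (take) { x <- xp; Ex <- Ep; acc <- acc + 1L } else rej <- rej + 1L
      }
      if (acc > rej) st[j] <- st[j] * exp(1 / acc)
      else if (rej > acc) st[j] <- st[j] * exp(-1 / rej)
    }
    live[worst, ] <- x
    E[worst] <- Ex
    steps[worst, ] <- st
    steps[src, ] <- st
    if (Ex < best_E) { best_E <- Ex; best <- x }
    n_done <- it
    if (!is.null(E_stop) && max(E) <= E_stop) break
    if (it %% 100 == 0) {
      cur <- colMeans(live)
      rel <- max(abs(cur - prev_mean) / pmax(abs(prev_mean), 1e-12))
      if (rel < stagnation) break
      prev_mean <- cur
    }
  }
  recorded <- recorded[seq_len(n_done), , drop = FALSE]
  rec_E <- rec_E[seq_len(n_done)]
  # burn-in: average over the recorded points that already explore the
  # data-compatible region (E < E_min); fall back to the post-burn-in tail
  # when the run never settles below E_min
  keep <- which(rec_E < E_min)
  if (length(keep) < 25) keep <- seq.int(floor(burn_in * n_done) + 1, n_done)
  structure(list(estimate = colMeans(recorded[keep, , drop = FALSE]),
                 best = best, best_energy = best_E,
                 recorded = cbind(recorded, energy = rec_E),
                 live = cbind(live, energy = E),
                 diagnostics = list(iterations = n_done, E_min = E_min,
                                    burn_in = burn_in,
                                    final_worst = max(E))),
            class = "cpch_fit")
}

#' @export
print.cpch_fit <- function(x, ...) {
  cat(sprintf("cpch_fit: %d replacements, best energy %.4g\n",
              x$diagnostics$iterations, x$best_energy))
  print(signif(rbind(estimate = x$estimate, best = x$best), 5))
  invisible(x)
}

# shared fast single-channel cumulant model used by the objectives:
# gamma_1 = 1, gamma_2 = 2^-1.5 fixed; gamma_3, gamma_4 free or fixed
.gamma_of_order <- function(tot, gamma3, gamma4) {
  g <- c(1, 2^-1.5, gamma3, gamma4)
  g[tot]
}

.kappa_1ch <- function(m, n, tau, tau_d, s) {
  x <- 2 * m * n * tau / ((m + n) * tau_d)
  (1 + x)^-1 * (1 + x / s^2)^-0.5
}

# per-row second-order binning evaluator for the fitters.
# binning = TRUE: continuous closed form; FALSE: no correction;
# "discrete": the acquisition is clocked at dt (the smallest bin), counts
# are snapshots frozen within a clock step, and a bin of K steps has the
# exact binning factor (1/K) + (2/K^2) sum_{k<K} (K-k) kappa_11(k dt)
.make_B2_fn <- function(binning, T, dt = min(T)) {
  if (isFALSE(binning)) return(function(tau_d, s) 1)
  if (identical(binning, "discrete")) {
    K <- as.integer(round(T / dt))
    uK <- sort(unique(K))
    Kmax <- max(uK)
    if (Kmax == 1L) return(function(tau_d, s) 1)
    kgrid <- seq_len(Kmax - 1L)
    W <- vapply(kgrid, function(k) ifelse(k < uK, 2 * (uK - k) / uK^2, 0),
                numeric(length(uK)))
    W <- matrix(W, nrow = length(uK))
    idx <- match(K, uK)
    tk <- kgrid * dt
    return(function(tau_d, s) {
      kap <- .kappa_1ch(1, 1, tk, tau_d, s)
      (1 / uK + as.vector(W %*% kap))[idx]
    })
  }
  function(tau_d, s) binning_B2(T, tau_d, 1 / s^2)
}

#' Factorial-cumulant fit of a single species (single channel)
#'
#' Fits `{N, eps, tau_d, s, gamma3, gamma4}` to an empirical factorial
#' cumulant table by minimising the cumulant fit energy with
#' [nested_sampling_fit()]. The model is
#' `(K)_{m,n} = gamma_{m+n} N eps^{m+n} kappa_{m,n}(tau; tau_d, s)
#'  B2(T, tau_d, 1/s^2)^(max(m-1,0) + max(n-1,0))`
#' with `gamma_1 = 1` and `gamma_2 = 2^(-3/2)` fixed (the amplitude
#' degeneracy leaves them unidentifiable) and `eps` in counts per bin `T`.
#'
#' @param emp_tab Empirical `cumulant_table` (single channel) with
#'   variances; its `T` column may vary by row (multi-tau scheme), in which
#'   case `eps` refers to counts per bin `T_ref`.
#' @param T_ref Reference bin time for the brightness parameter, s;
#'   defaults to the smallest `T` in the table.
#' @param lower,upper Named bounds for `N, eps, tau_d, s, gamma3, gamma4`.
#' @param binning Bin-time correction: `TRUE` uses the continuous closed
#'   form, `FALSE` none, and `"discrete"` models an acquisition clocked at
#'   the table's smallest bin, where counts are snapshots frozen within a
#'   clock step and a bin of K steps has the exact triangular binning sum
#'   of `kappa_{1,1}` (appropriate for discrete-time simulated data
#'   analysed at multiple bin sizes).
#' @param ... Passed to [nested_sampling_fit()].
#' @return A `cpch_fit`; `estimate` and `best` are named parameter vectors.
#' @export
fit_single_species <- function(emp_tab, T_ref = NULL,
                               lower = c(N = 0.05, eps = 0.005, tau_d = 5e-6,
                                         s = 1.05, gamma3 = 0.05, gamma4 = 0.02),
                               upper = c(N = 50, eps = 10, tau_d = 0.01,
                                         s = 10, gamma3 = 0.5, gamma4 = 0.4),
                               binning = TRUE, ...) {
  ok <- is.finite(emp_tab$variance) & emp_tab$variance > 0
  tab <- emp_tab[ok, ]
  m <- tab$m; n <- tab$n; tau <- tab$tau; T <- tab$T
  if (is.null(T_ref)) T_ref <- min(T)
  tot <- m + n
  val <- tab$value; vr <- tab$variance
  bexp <- pmax(m - 1, 0) + pmax(n - 1, 0)
  B2f <- .make_B2_fn(binning, T)
  Tfac <- (T / T_ref)^tot
  energy <- function(p) {
    K <- .gamma_of_order(tot, p["gamma3"], p["gamma4"]) * p["N"] *
      (p["eps"])^tot * Tfac * .kappa_1ch(m, n, tau, p["tau_d"], p["s"]) *
      B2f(p["tau_d"], p["s"])^bexp
    mean((K - val)^2 / vr)
  }
  nested_sampling_fit(energy, lower, upper,
                      log_scale = names(lower) == "tau_d", ...)
}

#' Factorial-cumulant fit of a two-species mixture (single channel)
#'
#' Fits `{N1, eps1, tau_d1, N2, eps2, tau_d2}` with the observation-volume
#' parameters held at their Gaussian values (`s` given, `gamma_n =
#' n^(-3/2)`). Species are identified by enforcing `eps1 >= eps2`. Initial
#' live points are drawn by [sample_parameter_sets()] from the 1D cumulants
#' at the shortest lag (brightness/occupancy), with diffusion times
#' log-uniform in their bounds.
#'
#' @param emp_tab Empirical `cumulant_table` with variances (per-row `T`
#'   supported as in [fit_single_species()]).
#' @param T_ref Reference bin time for the brightness parameters, s.
#' @param s Structure factor (fixed).
#' @param lower,upper Named bounds.
#' @param init_samples Draws used to seed the live set.
#' @param seed Seed applied before the initialisation draws (the sampler
#'   then continues the same stream), making the whole fit reproducible.
#' @param binning Bin-time correction: `TRUE` uses the continuous closed
#'   form, `FALSE` none, and `"discrete"` models an acquisition clocked at
#'   the table's smallest bin, where counts are snapshots frozen within a
#'   clock step and a bin of K steps has the exact triangular binning sum
#'   of `kappa_{1,1}` (appropriate for discrete-time simulated data
#'   analysed at multiple bin sizes).
#' @param ... Passed to [nested_sampling_fit()].
#' @return A `cpch_fit`.
#' @export
fit_two_species <- function(emp_tab, T_ref = NULL, s = 1.928,
                            lower = c(N1 = 0.05, eps1 = 0.005, tau_d1 = 5e-6,
                                      N2 = 0.05, eps2 = 0.005, tau_d2 = 5e-6),
                            upper = c(N1 = 50, eps1 = 10, tau_d1 = 0.01,
                                      N2 = 50, eps2 = 10, tau_d2 = 0.01),
                            init_samples = 2000, binning = TRUE,
                            seed = NULL, ...) {
  # the inversion-based initialisation draws random numbers before the
  # sampler starts, so the seed is applied here
  if (!is.null(seed)) set.seed(seed)
  ok <- is.finite(emp_tab$variance) & emp_tab$variance > 0
  tab <- emp_tab[ok, ]
  m <- tab$m; n <- tab$n; tau <- tab$tau; T <- tab$T
  if (is.null(T_ref)) T_ref <- min(T)
  tot <- m + n
  gam <- tot^-1.5
  val <- tab$value; vr <- tab$variance
  bexp <- pmax(m - 1, 0) + pmax(n - 1, 0)
  B2f <- .make_B2_fn(binning, T)
  Tfac <- (T / T_ref)^tot
  energy <- function(p) {
    if (p["eps1"] < p["eps2"]) return(Inf)
    K <- gam * Tfac * (p["N1"] * p["eps1"]^tot *
                         .kappa_1ch(m, n, tau, p["tau_d1"], s) *
                         B2f(p["tau_d1"], s)^bexp +
                       p["N2"] * p["eps2"]^tot *
                         .kappa_1ch(m, n, tau, p["tau_d2"], s) *
                         B2f(p["tau_d2"], s)^bexp)
    mean((K - val)^2 / vr)
  }
  # inversion-based initialisation from the 1D cumulants at the first lag
  init <- NULL
  t0 <- min(tab$tau)
  k1 <- vapply(1:4, function(nn) {
    r <- tab[tab$tau == t0 & tab$m == nn & tab$n == 0, ]
    if (nrow(r)) r$value[1] else NA_real_
  }, 0)
  v1 <- vapply(1:4, function(nn) {
    r <- tab[tab$tau == t0 & tab$m == nn & tab$n == 0, ]
    if (nrow(r)) r$variance[1] else NA_real_
  }, 0)
  if (!anyNA(k1) && !anyNA(v1)) {
    sm <- try(sample_parameter_sets(k1, v1, n_samples = init_samples),
              silent = TRUE)
    if (!inherits(sm, "try-error") && nrow(sm) > 0) {
      hi <- sm$eps1 >= sm$eps2
      sm[!hi, ] <- sm[!hi, c(3, 4, 1, 2)]
      nr <- nrow(sm)
      init <- cbind(N1 = sm$N1, eps1 = sm$eps1,
                    tau_d1 = exp(runif(nr, log(lower["tau_d1"]),
                                       log(upper["tau_d1"]))),
                    N2 = sm$N2, eps2 = sm$eps2,
                    tau_d2 = exp(runif(nr, log(lower["tau_d2"]),
                                       log(upper["tau_d2"]))))
    }
  }
  nested_sampling_fit(energy, lower, upper,
                      log_scale = grepl("^tau_d", names(lower)),
                      init = init, ...)
}

#' Spatial cPCH fit of a single species from image cumulants
#'
#' Fits `{N, eps, D, r, s, gamma3, gamma4}` to a spatial factorial-cumulant
#' table (from [spatial_cumulant_table()]): the lag of each pixel offset is
#' fixed by the scan geometry while the flow decay uses the physical pixel
#' displacement, so the diffusion coefficient `D` and the beam waist `r`
#' are separately identifiable. `eps` is in counts per pixel dwell.
#'
#' @param emp_tab Spatial `cumulant_table` with `d_x`, `d_y` columns.
#' @param geom The [scan_geometry()] of the acquisition.
#' @param lower,upper Named bounds (`r` in um, `D` in um^2/s).
#' @param binning Bin-time correction: `TRUE` uses the continuous closed
#'   form, `FALSE` none, and `"discrete"` models an acquisition clocked at
#'   the table's smallest bin, where counts are snapshots frozen within a
#'   clock step and a bin of K steps has the exact triangular binning sum
#'   of `kappa_{1,1}` (appropriate for discrete-time simulated data
#'   analysed at multiple bin sizes).
#' @param ... Passed to [nested_sampling_fit()].
#' @return A `cpch_fit`.
#' @export
fit_spatial <- function(emp_tab, geom,
                        lower = c(N = 0.02, eps = 0.01, D = 1, r = 0.1,
                                  s = 1.05, gamma3 = 0.05, gamma4 = 0.02),
                        upper = c(N = 50, eps = 20, D = 1000, r = 0.8,
                                  s = 10, gamma3 = 0.5, gamma4 = 0.4),
                        binning = TRUE, ...) {
  ok <- is.finite(emp_tab$variance) & emp_tab$variance > 0
  tab <- emp_tab[ok, ]
  m <- tab$m; n <- tab$n; tau <- tab$tau
  tot <- m + n
  disp2 <- (tab$d_x * geom$delta_x)^2 + (tab$d_y * geom$delta_y)^2
  val <- tab$value; vr <- tab$variance
  bexp <- if (binning) pmax(m - 1, 0) + pmax(n - 1, 0) else rep(0, length(m))
  T <- geom$dwell
  energy <- function(p) {
    tau_d <- p["r"]^2 / (4 * p["D"])
    x <- 2 * m * n * tau / ((m + n) * tau_d)
    kap <- (1 + x)^-1 * (1 + x / p["s"]^2)^-0.5
    S <- exp(-2 * m * n * disp2 / ((m + n) * p["r"]^2 * (1 + x)))
    K <- .gamma_of_order(tot, p["gamma3"], p["gamma4"]) * p["N"] *
      p["eps"]^tot * kap * S * binning_B2(T, tau_d, 1 / p["s"]^2)^bexp
    mean((K - val)^2 / vr)
  }
  nested_sampling_fit(energy, lower, upper,
                      log_scale = names(lower) == "D", ...)
}
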