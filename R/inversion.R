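#' Analytic two-species solution from 1D factorial cumulants
#'
#' Inverts the first four single-channel factorial cumulants
#' `(K)_n = gamma_n (N1 eps1^n + N2 eps2^n)` for the brightnesses and
#' occupancies of a two-species mixture. With `a_n = (K)_n / gamma_n`, the
#' brightnesses are the two roots of the quadratic `x^2 - p x + q` with
#' `p = (a1 a4 - a2 a3) / (a1 a3 - a2^2)` and
#' `q = (a2 a4 - a3^2) / (a1 a3 - a2^2)` (a two-point Prony system), and
#' the occupancies follow linearly. The solution is unique up to species
#' relabelling; the result is labelled with `eps1 >= eps2`.
#'
#' Noisy cumulants can produce complex or negative roots; these are
#' returned flagged non-physical rather than as errors. Data from a single
#' species make the denominator `a1 a3 - a2^2` vanish; this degenerate case
#' falls back to the single-species solution `eps = a2/a1, N = a1^2/a2`.
#'
#' @param K Numeric vector of factorial cumulants `(K)_1 .. (K)_4`.
#' @param gamma Shape factors `gamma_1 .. gamma_4` (e.g. `(1:4)^-1.5`).
#' @return Object of class `two_species_solution`: `N1, eps1, N2, eps2`,
#'   logical `physical`, logical `degenerate`, and the inputs.
#' @export
invert_two_species <- function(K, gamma = (1:4)^-1.5) {
  if (length(K) != 4 || length(gamma) != 4) .stopf("need orders 1..4")
  if (any(!is.finite(K)) || any(gamma <= 0)) .stopf("invalid cumulants or gammas")
  a <- K / gamma
  den <- a[1] * a[3] - a[2]^2
  scale <- abs(a[1] * a[3]) + a[2]^2
  out <- list(K = K, gamma = gamma, degenerate = FALSE, physical = FALSE,
              N1 = NA_real_, eps1 = NA_real_, N2 = NA_real_, eps2 = NA_real_)
  if (scale == 0 || abs(den) < 1e-12 * scale) {
    out$degenerate <- TRUE
    if (a[1] > 0 && a[2] > 0) {
      out$eps1 <- a[2] / a[1]
      out$N1 <- a[1]^2 / a[2]
      out$N2 <- 0; out$eps2 <- 0
      out$physical <- TRUE
    }
    class(out) <- "two_species_solution"
    return(out)
  }
  p <- (a[1] * a[4] - a[2] * a[3]) / den
  q <- (a[2] * a[4] - a[3]^2) / den
  disc <- p^2 - 4 * q
  if (!is.finite(disc) || disc < 0) {
    class(out) <- "two_species_solution"
    return(out)
  }
  e1 <- (p + sqrt(disc)) / 2
  e2 <- (p - sqrt(disc)) / 2
  if (e1 <= 0 || e2 <= 0 || e1 == e2) {
    class(out) <- "two_species_solution"
    return(out)
  }
  N1 <- (a[2] - e2 * a[1]) / (e1 * (e1 - e2))
  N2 <- (a[1] - N1 * e1) / e2
  out$N1 <- N1; out$eps1 <- e1; out$N2 <- N2; out$eps2 <- e2
  out$physical <- is.finite(N1) && is.finite(N2) && N1 >= 0 && N2 >= 0
  class(out) <- "two_species_solution"
  out
}

#' @export
print.two_species_solution <- function(x, ...) {
  cat(sprintf("two_species_solution: N1=%.4g eps1=%.4g N2=%.4g eps2=%.4g (%s%s)\n",
              x$N1, x$eps1, x$N2, x$eps2,
              if (x$physical) "physical" else "non-physical",
              if (x$degenerate) ", degenerate/single-species" else ""))
  invisible(x)
}

#' Forward two-species factorial cumulants
#'
#' `(K)_n = gamma_n (N1 eps1^n + N2 eps2^n)` for `n = 1..4`; the forward
#' map inverted by [invert_two_species()].
#'
#' @param N1,eps1,N2,eps2 Mixture parameters.
#' @param gamma Shape factors `gamma_1..gamma_4`.
#' @return Numeric vector of length 4.
#' @export
two_species_cumulants <- function(N1, eps1, N2, eps2, gamma = (1:4)^-1.5) {
  n <- 1:4
  gamma * (N1 * eps1^n + N2 * eps2^n)
}

#' Sample physical two-species solutions within experimental error
#'
#' Resamples each empirical factorial cumulant independently from a
#' Gaussian with its moments-of-moments variance, inverts each draw, and
#' keeps the physical solutions. The yield fraction falls as the cumulant
#' errors grow, which itself is diagnostic of insufficient data. Uses R's
#' RNG stream (set a seed for reproducibility).
#'
#' @param K Empirical factorial cumulants `(K)_1..(K)_4`.
#' @param variance Their variances.
#' @param gamma Shape factors.
#' @param n_samples Number of draws.
#' @param seed Optional seed applied via [set.seed()].
#' @return Data frame with columns `N1, eps1, N2, eps2` (one row per
#'   physical draw) and attribute `yield` (fraction physical). Errors if no
#'   draw is physical, with guidance.
#' @export
sample_parameter_sets <- function(K, variance, gamma = (1:4)^-1.5,
                                  n_samples = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(variance < 0)) .stopf("variances must be non-negative")
  draws <- matrix(rnorm(4 * n_samples, mean = rep(K, each = n_samples),
                        sd = rep(sqrt(variance), each = n_samples)),
                  ncol = 4)
  sols <- apply(draws, 1, function(k) {
    s <- invert_two_species(k, gamma)
    if (s$physical && !s$degenerate) c(s$N1, s$eps1, s$N2, s$eps2) else rep(NA_real_, 4)
  })
  sols <- t(sols)
  ok <- stats::complete.cases(sols)
  if (!any(ok))
    .stopf(paste("no physical two-species solution within the sampled errors;",
                 "collect more data or fit the joint (tau > 0) cumulants"))
  out <- as.data.frame(sols[ok, , drop = FALSE])
  names(out) <- c("N1", "eps1", "N2", "eps2")
  attr(out, "yield") <- mean(ok)
  out
}
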