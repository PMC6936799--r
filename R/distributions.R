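#' Joint photon-count PMF container
#'
#' @param values Matrix of probabilities over counts `0..(nrow-1)` (first
#'   channel, rows) and `0..(ncol-1)` (second channel, columns).
#' @param tau,T Lag and bin time, s.
#' @param kind Descriptive label.
#' @return Object of class `joint_pmf`.
#' @keywords internal
joint_pmf <- function(values, tau, T, kind = "joint") {
  structure(list(values = values, tau = tau, T = T, kind = kind),
            class = "joint_pmf")
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf("joint_pmf (%s): %d x %d counts, tau=%g s, T=%g s, sum=%.8f\n",
              x$kind, nrow(x$values), ncol(x$values), x$tau, x$T,
              sum(x$values)))
  invisible(x)
}

# factorial-moment matrix (M)_{m,n}(tau, T) of a single molecule,
# orders 0..Mmax x 0..Nmax; (M)_{0,0} = 1
.fac_moment_matrix <- function(Mmax, Nmax, eA, eB, tau, T, D, optical) {
  g <- expand.grid(m = 0:Mmax, n = 0:Nmax)
  keep <- g$m + g$n >= 1
  out <- matrix(0, Mmax + 1, Nmax + 1)
  out[1, 1] <- 1
  m <- g$m[keep]; n <- g$n[keep]
  beta_A <- (optical$r_A / optical$z_A)^2
  beta_B <- (optical$r_B / optical$z_B)^2
  tau_A <- optical$r_A^2 / (4 * D)
  tau_B <- optical$r_B^2 / (4 * D)
  val <- eA^m * eB^n * shape_factor(m, n, optical) *
    diffusion_factor(m, n, tau, D, optical) *
    binning_Bmn(m, n, T, tau_A, tau_B, beta_A, beta_B)
  out[cbind(m + 1, n + 1)] <- val
  out
}

#' Single-molecule joint count distribution (series route)
#'
#' Evaluates the alternating series expressing the single-molecule joint
#' count probability in terms of its factorial moments:
#' `p1(nx, ny) = sum_k (-1)^k / (nx! ny! k!) sum_m C(k, m)
#' (M)_{nx+k-m, ny+m}`. Factorial moments carry the diffusion factor at lag
#' `tau` and the product binning approximation at bin time `T`. The series
#' is truncated adaptively once the largest absolute contribution of a term
#' falls below `tol`; it diverges for bright molecules, in which case an
#' error suggests the FFT route (which only ever needs this series for the
#' same dim single-molecule inputs).
#'
#' @param species A [species_params()] (brightness in counts/s unless the
#'   object says otherwise).
#' @param optical An [optical_config()].
#' @param tau Lag, s.
#' @param T Bin time, s.
#' @param max_counts Largest count per axis (grid is `0..max_counts`).
#' @param tol Truncation tolerance on the series terms.
#' @param k_cap Hard cap on the series index.
#' @return A `joint_pmf` with attribute `k_used`.
#' @export
p1_series <- function(species, optical, tau, T, max_counts = 20,
                      tol = 1e-14, k_cap = 200) {
  stopifnot(inherits(species, "species_params"), inherits(optical, "optical_config"))
  if (tol <= 0) .stopf("tol must be positive")
  if (species$eps_unit == "counts_per_s") {
    eA <- species$eps_A * T; eB <- species$eps_B * T
  } else {
    eA <- species$eps_A; eB <- species$eps_B
  }
  D <- if (is.null(species$D)) optical$r_A^2 / (4 * species$tau_d) else species$D
  L <- max_counts + 1
  if (eA == 0 && eB == 0) {
    v <- matrix(0, L, L)
    v[1, 1] <- 1
    return(joint_pmf(v, tau, T, "single_molecule"))
  }
  chunk <- 64L
  Mmax <- L - 1 + chunk
  fm <- .fac_moment_matrix(Mmax, Mmax, eA, eB, tau, T, D, optical)
  p <- matrix(0, L, L)
  lf <- lgamma(1:L)                       # log((nx)!) for nx = 0..L-1
  inv_fact <- exp(-outer(lf, lf, "+"))    # 1/(nx! ny!)
  k <- 0L
  small_run <- 0L
  repeat {
    if (L - 1 + k > Mmax) {
      Mmax <- Mmax + chunk
      fm <- .fac_moment_matrix(Mmax, Mmax, eA, eB, tau, T, D, optical)
    }
    A <- matrix(0, L, L)
    for (mm in 0:k)
      A <- A + choose(k, mm) * fm[(k - mm) + (1:L), mm + (1:L)]
    contrib <- ((-1)^k / factorial(k)) * inv_fact * A
    p <- p + contrib
    mx <- max(abs(contrib))
    small_run <- if (mx < tol) small_run + 1L else 0L
    if (small_run >= 2L) break
    k <- k + 1L
    if (k > k_cap)
      .stopf(paste("series for p1 did not converge within %d terms",
                   "(molecule too bright for the series route); use pN_fft"),
             k_cap)
  }
  p[p < 0 & p > -1e-12] <- 0
  out <- joint_pmf(p, tau, T, "single_molecule")
  out$k_used <- k
  out
}

# grid size heuristic: compound-Poisson tail bound per channel
.grid_size <- function(model, T, channel = c("A", "B")) {
  channel <- match.arg(channel)
  mu <- factorial_cumulant(as.integer(channel == "A"),
                           as.integer(channel == "B"), 0, T, model)
  emax <- max(vapply(model$species, function(sp)
    (if (channel == "A") sp$eps_A else sp$eps_B) * T, 0))
  need <- mu + 10 * sqrt(mu + 1) + 12 * emax + 8
  2^ceiling(log2(need))
}

#' N-molecule cPCH distribution via generating functions and the FFT
#'
#' Composes the compound-Poisson characteristic function
#' `exp(sum_q N_q (g1_q - 1) + background)` on a discrete Fourier grid from
#' the single-molecule distributions of [p1_series()] and inverts it.
#' Backgrounds enter through the log-transform of the product-Poisson PMF.
#' Negative entries from FFT ringing (bounded by 1e-12) are clipped and the
#' distribution renormalised; the grid doubles the tail-bound size to
#' suppress circular aliasing and is cropped on return.
#'
#' @param model A [cpch_model()].
#' @param tau Lag, s.
#' @param T Bin time, s.
#' @param L_t,L_s Optional grid sizes (counts per axis) before padding;
#'   chosen from a tail bound when `NULL`.
#' @return A `joint_pmf`.
#' @export
pN_fft <- function(model, tau, T, L_t = NULL, L_s = NULL) {
  stopifnot(inherits(model, "cpch_model"))
  if (is.null(L_t)) L_t <- .grid_size(model, T, "A")
  if (is.null(L_s)) L_s <- .grid_size(model, T, "B")
  Lt2 <- 2L * L_t; Ls2 <- 2L * L_s
  acc <- matrix(0 + 0i, Lt2, Ls2)
  for (sp in model$species) {
    if (sp$N == 0) next
    p1 <- p1_series(sp, model$optical, tau, T, max_counts = max(Lt2, Ls2) - 1)
    g1 <- fft(p1$values[1:Lt2, 1:Ls2])
    acc <- acc + sp$N * (g1 - 1)
  }
  lamA <- model$lambda_A * T / model$T_ref
  lamB <- model$lambda_B * T / model$T_ref
  wA <- exp(-2i * pi * (0:(Lt2 - 1)) / Lt2)
  wB <- exp(-2i * pi * (0:(Ls2 - 1)) / Ls2)
  bg <- outer(lamA * (wA - 1), rep(1, Ls2)) + outer(rep(1, Lt2), lamB * (wB - 1))
  p <- Re(fft(exp(acc + bg), inverse = TRUE)) / (Lt2 * Ls2)
  if (min(p) < -1e-9)
    .stopf("FFT route produced negative probabilities beyond tolerance (%.3g)",
           min(p))
  clip <- -sum(p[p < 0])
  if (clip > 1e-6) .stopf("clipped probability mass %.3g exceeds 1e-6", clip)
  p[p < 0] <- 0
  # post-hoc tail check on the content region
  tail_mass <- 1 - sum(p[1:L_t, 1:L_s])
  if (tail_mass > 1e-7)
    .stopf("tail mass %.3g outside the count grid; enlarge L_t/L_s", tail_mass)
  p <- p[1:L_t, 1:L_s]
  p <- p / sum(p)
  out <- joint_pmf(p, tau, T, "cpch")
  out$clip <- clip
  out
}

#' N-molecule cPCH distribution via recursion
#'
#' Independent route to the same distribution as [pN_fft()]: a bivariate
#' compound-Poisson recursion seeded at
#' `p(0,0) = exp(-sum_i N_i (1 - p1_i(0,0)) - lambda_A - lambda_B)`,
#' then filled along the `n_x = 0` edge, the `n_y = 0` edge, and the
#' interior, in that order.
#'
#' @param model A [cpch_model()].
#' @param tau Lag, s.
#' @param T Bin time, s.
#' @param max_counts Largest count per axis.
#' @return A `joint_pmf`.
#' @export
pN_recursion <- function(model, tau, T, max_counts = 20) {
  stopifnot(inherits(model, "cpch_model"))
  L <- max_counts + 1L
  p1s <- lapply(model$species, function(sp)
    p1_series(sp, model$optical, tau, T, max_counts = max_counts)$values)
  lamA <- model$lambda_A * T / model$T_ref
  lamB <- model$lambda_B * T / model$T_ref
  P <- .pn_recursion_cpp(p1s, vapply(model$species, `[[`, 0, "N"),
                         lamA, lamB, L, L)
  joint_pmf(P, tau, T, "cpch")
}

#' Single-channel PCH as a marginal of the cPCH distribution
#'
#' Sums the joint distribution over one axis. The marginal is independent
#' of the lag `tau`, which provides a useful internal consistency check.
#'
#' @param pmf A `joint_pmf`.
#' @param axis Axis to keep: 1 (first channel) or 2.
#' @return Numeric vector of probabilities over counts `0..L-1`.
#' @export
pch_marginal <- function(pmf, axis = 1) {
  stopifnot(inherits(pmf, "joint_pmf"))
  if (axis == 1) rowSums(pmf$values) else colSums(pmf$values)
}

#' Dual-colour PCH (zero-lag cPCH)
#'
#' At `tau = 0` with two distinct detection channels the cPCH distribution
#' is the dual-colour PCH. With a single channel compared against itself at
#' zero lag, counts on the two axes are identical by construction, so the
#' distribution is one-dimensional: this case returns a diagonal-only
#' matrix (with a warning), whose diagonal is the ordinary PCH.
#'
#' @param model A [cpch_model()].
#' @param T Bin time, s.
#' @param single_channel Set `TRUE` when both axes come from the same
#'   detector.
#' @param max_counts Grid size for the single-channel (diagonal) mode.
#' @return A `joint_pmf`.
#' @export
dual_color_pch <- function(model, T, single_channel = FALSE, max_counts = 20) {
  if (!single_channel) return(pN_fft(model, 0, T))
  .warnf("single-channel zero-lag cPCH is diagonal; returning diagonal form")
  pmf <- pN_fft(model, max(model$T_ref, T), T, L_t = max_counts + 1,
                L_s = max_counts + 1)
  pch <- pch_marginal(pmf, 1)
  joint_pmf(diag(pch), 0, T, "cpch_diagonal")
}

#' Raw moments of a PMF by direct summation
#'
#' @param pmf A `joint_pmf` (or bare matrix).
#' @param max_m,max_n Maximum orders.
#' @return Matrix of raw moments indexed `[m + 1, n + 1]`.
#' @export
pmf_moments <- function(pmf, max_m = 4, max_n = 4) {
  v <- if (inherits(pmf, "joint_pmf")) pmf$values else pmf
  nx <- 0:(nrow(v) - 1); ny <- 0:(ncol(v) - 1)
  out <- matrix(0, max_m + 1, max_n + 1)
  for (m in 0:max_m) for (n in 0:max_n)
    out[m + 1, n + 1] <- sum(outer(nx^m, ny^n) * v)
  out
}

#' Sample count pairs from a joint PMF
#'
#' Draws independent (n_x, n_y) pairs; uses R's RNG stream.
#'
#' @param pmf A `joint_pmf`.
#' @param n Number of draws.
#' @return Two-column integer matrix.
#' @export
sample_joint_pmf <- function(pmf, n) {
  v <- pmf$values
  idx <- sample.int(length(v), n, replace = TRUE, prob = as.vector(v))
  cbind(n_x = (idx - 1) %% nrow(v), n_y = (idx - 1) %/% nrow(v))
}
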