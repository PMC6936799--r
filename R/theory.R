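#' Optical configuration of the two detection channels
#'
#' Describes one or two 3D Gaussian observation volumes by their radial and
#' axial 1/e^2 beam-waist parameters. For single-channel (autocorrelation)
#' analyses both channels share the same geometry, which is the default.
#'
#' @param r_A,z_A Radial and axial beam-waist parameters of channel A, in
#'   micrometres.
#' @param r_B,z_B Geometry of channel B; default to channel A.
#' @return An object of class `optical_config` with fields `r_A`, `z_A`,
#'   `r_B`, `z_B`, the structure factor `s = z_A / r_A` and a flag
#'   `identical` when the two channels coincide.
#' @examples
#' opt <- optical_config(r_A = 0.2651, z_A = 1.928 * 0.2651)
#' observation_volume(opt)
#' @export
optical_config <- function(r_A, z_A, r_B = r_A, z_B = z_A) {
  v <- c(r_A = r_A, z_A = z_A, r_B = r_B, z_B = z_B)
  if (any(!is.finite(v)) || any(v <= 0))
    .stopf("beam-waist parameters must be finite and strictly positive")
  structure(list(r_A = r_A, z_A = z_A, r_B = r_B, z_B = z_B,
                 s = z_A / r_A,
                 identical = (r_A == r_B && z_A == z_B)),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("optical_config: r_A=%g z_A=%g r_B=%g z_B=%g (s=%.4g%s)\n",
              x$r_A, x$z_A, x$r_B, x$z_B, x$s,
              if (x$identical) ", identical channels" else ""))
  invisible(x)
}

#' Two-channel observation volume
#'
#' Effective observation volume of a pair of 3D Gaussian beams,
#' `(pi/2)^(3/2) ((r_A^2 + r_B^2)/2) sqrt((z_A^2 + z_B^2)/2)`, in cubic
#' micrometres. For identical channels this reduces to
#' `(pi/2)^(3/2) r^2 z`.
#'
#' @param optical An [optical_config()].
#' @return Volume in um^3.
#' @export
observation_volume <- function(optical) {
  stopifnot(inherits(optical, "optical_config"))
  (pi / 2)^1.5 * ((optical$r_A^2 + optical$r_B^2) / 2) *
    sqrt((optical$z_A^2 + optical$z_B^2) / 2)
}

#' Shape factors of the observation volume
#'
#' Normalised spatial moments `gamma_{m,n}` of the product of the two
#' Gaussian intensity profiles, i.e. the integral of
#' `(I_A/eps_A)^m (I_B/eps_B)^n` over space divided by the observation
#' volume. For identical channels `gamma_{m,n} = (m+n)^(-3/2)`.
#'
#' @param m,n Non-negative integer orders with `m + n >= 1` (vectorised,
#'   recycled against each other).
#' @param optical An [optical_config()].
#' @return Shape factor(s), dimensionless.
#' @examples
#' opt <- optical_config(0.25, 1.25)
#' shape_factor(3, 0, opt)  # 3^(-3/2) = 0.192
#' @export
shape_factor <- function(m, n, optical) {
  stopifnot(inherits(optical, "optical_config"))
  k <- .check_orders(m, n)
  m <- k$m; n <- k$n
  rA2 <- optical$r_A^2; rB2 <- optical$r_B^2
  zA2 <- optical$z_A^2; zB2 <- optical$z_B^2
  2^1.5 * rA2 * rB2 * optical$z_A * optical$z_B /
    ((n * rA2 + m * rB2) * (rA2 + rB2) *
       sqrt(n * zA2 + m * zB2) * sqrt(zA2 + zB2))
}

.check_orders <- function(m, n) {
  k <- max(length(m), length(n))
  m <- rep_len(m, k); n <- rep_len(n, k)
  if (any(m < 0 | n < 0 | (m + n) < 1) || any(m != round(m) | n != round(n)))
    .stopf("orders must be non-negative integers with m + n >= 1")
  list(m = m, n = n)
}

#' Diffusion factor of the higher-order correlation function
#'
#' Lag-time decay `kappa_{m,n}(tau, D)` of the order-(m, n) two-point
#' correlation for free 3D diffusion through Gaussian observation volumes:
#' a Lorentzian-type radial factor and a square-root axial factor. Equals 1
#' at `tau = 0` and whenever `m` or `n` is zero, and decays to 0 as
#' `tau -> Inf` (for `m, n >= 1`).
#'
#' @param m,n Orders (vectorised).
#' @param tau Lag time(s) in seconds, `>= 0`.
#' @param D Diffusion coefficient in um^2/s, `>= 0`.
#' @param optical An [optical_config()].
#' @return Value(s) in (0, 1].
#' @export
diffusion_factor <- function(m, n, tau, D, optical) {
  stopifnot(inherits(optical, "optical_config"))
  if (any(tau < 0) || any(D < 0) || any(!is.finite(tau)) || !all(is.finite(D)))
    .stopf("tau and D must be finite and non-negative")
  k <- .check_orders(m, n)
  m <- k$m; n <- k$n
  rA2 <- optical$r_A^2; rB2 <- optical$r_B^2
  zA2 <- optical$z_A^2; zB2 <- optical$z_B^2
  x <- 8 * m * n * D * tau
  (1 + x / (n * rA2 + m * rB2))^-1 * (1 + x / (n * zA2 + m * zB2))^-0.5
}

#' Flow (scanning) factor of the correlation function
#'
#' Gaussian decay `S_{m,n}` contributed by a uniform flow (or an equivalent
#' scanner displacement) with velocity components `v_x`, `v_y` in the focal
#' plane. Equals 1 when `v_x = v_y = 0`.
#'
#' The displacement entering the decay is `v * tau`; for raster-scanned
#' images, pass the pixel displacement divided by the lag as the velocity
#' (see [offset_to_tau()]).
#'
#' @param m,n Orders (vectorised).
#' @param tau Lag time(s), s.
#' @param D Diffusion coefficient, um^2/s.
#' @param v_x,v_y Flow velocity components, um/s.
#' @param optical An [optical_config()].
#' @return Value(s) in (0, 1].
#' @export
flow_factor <- function(m, n, tau, D, v_x, v_y, optical) {
  stopifnot(inherits(optical, "optical_config"))
  if (!all(is.finite(c(v_x, v_y)))) .stopf("flow velocities must be finite")
  k <- .check_orders(m, n)
  m <- k$m; n <- k$n
  rA2 <- optical$r_A^2; rB2 <- optical$r_B^2
  den <- (n * rA2 + m * rB2) * (1 + 8 * m * n * D * tau / (n * rA2 + m * rB2))
  exp(-2 * m * n * tau^2 * (v_x^2 + v_y^2) / den)
}

#' Per-species parameters
#'
#' @param N Mean number of molecules of the species in the observation
#'   volume (dimensionless occupancy).
#' @param eps_A,eps_B Molecular brightness in channels A and B. By default
#'   interpreted as count rates in counts/s (`eps_unit = "counts_per_s"`);
#'   counts-per-bin values are converted to rates using the model's
#'   reference bin time when the species is placed in a [cpch_model()].
#' @param D Diffusion coefficient, um^2/s. Exactly one of `D` and `tau_d`
#'   must be given; the other is derived (via `tau_d = r_A^2 / (4 D)`) once
#'   the optical geometry is known.
#' @param tau_d Radial diffusion time through channel A, seconds.
#' @param eps_unit Unit of `eps_A`/`eps_B`.
#' @return An object of class `species_params`.
#' @export
species_params <- function(N, eps_A, eps_B = eps_A, D = NULL, tau_d = NULL,
                           eps_unit = c("counts_per_s", "counts_per_bin")) {
  eps_unit <- match.arg(eps_unit)
  if (N < 0 || eps_A < 0 || eps_B < 0)
    .stopf("N and brightnesses must be non-negative")
  if (is.null(D) == is.null(tau_d))
    .stopf("exactly one of D and tau_d must be supplied")
  if (!is.null(D) && D < 0) .stopf("D must be non-negative")
  if (!is.null(tau_d) && tau_d <= 0) .stopf("tau_d must be positive")
  structure(list(N = N, eps_A = eps_A, eps_B = eps_B, D = D, tau_d = tau_d,
                 eps_unit = eps_unit),
            class = "species_params")
}

#' cPCH model: optics, species mixture, background and optional flow
#'
#' Bundles an optical configuration with a list of independent fluorescent
#' species, Poisson background rates and an optional flow. Brightnesses are
#' stored internally as count rates (counts/s); counts-per-bin inputs are
#' converted at the reference bin time `T_ref`. Backgrounds `lambda_A`,
#' `lambda_B` are given in counts per bin of duration `T_ref`.
#'
#' @param optical An [optical_config()].
#' @param species A `species_params` object or list of them.
#' @param T_ref Reference bin time, seconds.
#' @param lambda_A,lambda_B Background, counts per `T_ref` bin.
#' @param flow Optional numeric `c(v_x, v_y)` in um/s.
#' @return An object of class `cpch_model`. Each species gains resolved
#'   fields `D`, `tau_A`, `tau_B` (radial diffusion times per channel) and
#'   `eps_A`/`eps_B` in counts/s.
#' @export
cpch_model <- function(optical, species, T_ref, lambda_A = 0, lambda_B = 0,
                       flow = NULL) {
  stopifnot(inherits(optical, "optical_config"))
  if (inherits(species, "species_params")) species <- list(species)
  if (length(species) < 1) .stopf("at least one species is required")
  if (T_ref <= 0) .stopf("T_ref must be positive")
  if (lambda_A < 0 || lambda_B < 0) .stopf("backgrounds must be non-negative")
  if (!is.null(flow) && (length(flow) != 2 || !all(is.finite(flow))))
    .stopf("flow must be c(v_x, v_y)")
  species <- lapply(species, function(sp) {
    stopifnot(inherits(sp, "species_params"))
    if (sp$eps_unit == "counts_per_bin") {
      sp$eps_A <- sp$eps_A / T_ref
      sp$eps_B <- sp$eps_B / T_ref
      sp$eps_unit <- "counts_per_s"
    }
    if (is.null(sp$D)) sp$D <- optical$r_A^2 / (4 * sp$tau_d)
    sp$tau_A <- optical$r_A^2 / (4 * sp$D)
    sp$tau_B <- optical$r_B^2 / (4 * sp$D)
    sp$tau_d <- sp$tau_A
    sp
  })
  structure(list(optical = optical, species = species, T_ref = T_ref,
                 lambda_A = lambda_A, lambda_B = lambda_B, flow = flow),
            class = "cpch_model")
}

#' @export
print.cpch_model <- function(x, ...) {
  cat(sprintf("cpch_model: %d species, T_ref=%g s, background (%g, %g) counts/bin\n",
              length(x$species), x$T_ref, x$lambda_A, x$lambda_B))
  for (sp in x$species)
    cat(sprintf("  N=%g eps_A=%g eps_B=%g counts/s, D=%g um^2/s (tau_d=%g s)\n",
                sp$N, sp$eps_A, sp$eps_B, sp$D, sp$tau_d))
  invisible(x)
}

#' Lag/bin scheme
#'
#' A set of (tau, T) pairs on the detector clock. Each bin time `T` must be
#' an integer multiple of the sampling time, and each lag `tau` an integer
#' multiple of its `T`.
#'
#' @param tau Lag times, seconds.
#' @param T Bin times, seconds (scalar or one per lag).
#' @param sampling_time Detector clock period, seconds.
#' @return A data frame of class `bin_scheme` with columns `tau`, `T`,
#'   `tau_k` (lag in units of `T`) and `T_s` (bin in sampling ticks).
#' @export
bin_scheme <- function(tau, T, sampling_time) {
  T <- rep_len(T, length(tau))
  if (any(tau < 0) || any(T <= 0) || sampling_time <= 0)
    .stopf("tau >= 0, T > 0 and sampling_time > 0 required")
  T_s <- T / sampling_time
  tau_k <- tau / T
  if (any(abs(T_s - round(T_s)) > 1e-6))
    .stopf("T must be an integer multiple of the sampling time")
  if (any(abs(tau_k - round(tau_k)) > 1e-6))
    .stopf("tau must be an integer multiple of T")
  structure(data.frame(tau = tau, T = T, tau_k = as.integer(round(tau_k)),
                       T_s = as.integer(round(T_s))),
            class = c("bin_scheme", "data.frame"),
            sampling_time = sampling_time)
}

#' Second-order binning function
#'
#' Correction for molecular motion during a counting bin of length `T`
#' relative to the diffusion time `tau_d`, for a 3D Gaussian observation
#' volume. Defined as the doubly time-averaged pair correlation
#' `(2/T^2) * integral_0^T (T - t) kappa_{1,1}(t) dt`; evaluated in closed
#' form with `alpha = T/tau_d` and `beta = (r/z)^2`. Tends to 1 as
#' `alpha -> 0` and decreases monotonically in `alpha`.
#'
#' `beta` is clamped to `[1e-6, 1 - 1e-9]` to stay inside the branch
#' limits of the `atanh` term as the structure factor approaches 1.
#'
#' @param T Bin time(s), s.
#' @param tau_d Diffusion time, s.
#' @param beta Squared radial-to-axial waist ratio, in (0, 1].
#' @return B2 value(s) in (0, 1].
#' @export
binning_B2 <- function(T, tau_d, beta) {
  if (any(T <= 0) || any(tau_d <= 0)) .stopf("T and tau_d must be positive")
  if (any(beta <= 0) || any(beta > 1)) .stopf("beta must lie in (0, 1]")
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-9)
  alpha <- T / tau_d
  k <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, k); beta <- rep_len(beta, k)
  out <- numeric(k)
  # three regimes guard against cancellation in the closed form, whose
  # bracket is O(alpha^2 beta / 4) and loses all precision when that
  # approaches machine epsilon
  small <- alpha < 1e-5
  flatz <- !small & (alpha^2 * beta < 1e-7)
  closed <- !small & !flatz
  if (any(small)) {
    a <- alpha[small]; b <- beta[small]
    # series of the defining integral: 1 - c1*a/3 + c2*a^2/6
    c1 <- 1 + b / 2
    c2 <- 1 + b / 2 + 3 * b^2 / 8
    out[small] <- 1 - c1 * a / 3 + c2 * a^2 / 6
  }
  if (any(flatz)) {
    # beta -> 0 limit (purely radial decay) with its first-order beta term
    a <- alpha[flatz]; b <- beta[flatz]
    b0 <- 2 / a^2 * ((1 + a) * log1p(a) - a)
    out[flatz] <- b0 - b / a^2 * (a^2 / 2 - ((1 + a) * log1p(a) - a))
  }
  if (any(closed)) {
    a <- alpha[closed]; b <- beta[closed]
    W <- sqrt(1 + b * a)
    cc <- sqrt(1 - b)
    at <- atanh(cc * (W - 1) / (b + W - 1))
    out[closed] <- 4 / (a^2 * b) * (b * (1 + a) / cc * at + 1 - W)
  }
  out
}

#' Higher-order binning functions (product approximation)
#'
#' Approximates the order-(m, n) binning function by products of powers of
#' the second-order function, one factor per channel:
#' `B2(T, tau_A)^(m-1) * B2(T, tau_B)^(n-1)` (each factor present only when
#' its order exceeds 1). `B_{1,0} = B_{0,1} = B_{1,1} = 1`.
#'
#' @param m,n Orders (vectorised).
#' @param T Bin time, s.
#' @param tau_A,tau_B Radial diffusion times per channel, s.
#' @param beta_A,beta_B Squared waist ratios per channel.
#' @return B value(s).
#' @export
binning_Bmn <- function(m, n, T, tau_A, tau_B = tau_A,
                        beta_A, beta_B = beta_A) {
  k <- .check_orders(m, n)
  m <- k$m; n <- k$n
  bA <- binning_B2(T, tau_A, beta_A)
  bB <- binning_B2(T, tau_B, beta_B)
  out <- rep_len(1, length(m))
  ia <- m > 1; ib <- n > 1
  out[ia] <- out[ia] * rep_len(bA, length(m))[ia]^(m[ia] - 1)
  out[ib] <- out[ib] * rep_len(bB, length(n))[ib]^(n[ib] - 1)
  out
}

#' Higher-order two-point correlation function
#'
#' `G_{m,n}(tau) = eps_A^m eps_B^n gamma_{m,n} kappa_{m,n}(tau, D)`, with an
#' additional flow factor when `flow` is supplied. Brightness units are
#' counts per bin: when the species stores count rates, supply `T` so that
#' `eps = eps_o * T`.
#'
#' @param m,n Orders (vectorised).
#' @param tau Lag time(s), s.
#' @param species A [species_params()].
#' @param optical An [optical_config()].
#' @param flow Optional `c(v_x, v_y)` in um/s.
#' @param T Bin time used to convert count rates to counts/bin; required
#'   when the species brightness is in counts/s.
#' @return G value(s), in (counts/bin)^(m+n).
#' @export
correlation_G <- function(m, n, tau, species, optical, flow = NULL, T = NULL) {
  stopifnot(inherits(species, "species_params"), inherits(optical, "optical_config"))
  k <- .check_orders(m, n)
  m <- k$m; n <- k$n
  if (species$eps_unit == "counts_per_s") {
    if (is.null(T)) .stopf("T is required when brightness is in counts/s")
    eA <- species$eps_A * T; eB <- species$eps_B * T
  } else {
    eA <- species$eps_A; eB <- species$eps_B
  }
  D <- if (is.null(species$D)) optical$r_A^2 / (4 * species$tau_d) else species$D
  g <- eA^m * eB^n * shape_factor(m, n, optical) *
    diffusion_factor(m, n, tau, D, optical)
  if (!is.null(flow))
    g <- g * flow_factor(m, n, tau, D, flow[1], flow[2], optical)
  g
}

#' Factorial cumulants of a cPCH model
#'
#' Closed-form factorial cumulants `(K)_{m,n}(tau, T)` of the joint photon
#' count distribution for a mixture of independent species with Poisson
#' backgrounds. First-order cumulants are
#' `lambda + sum_i N_i eps_i T gamma` (background enters only at first
#' order); higher orders are
#' `gamma_{m,n} sum_i N_i (eps_Ai T)^m (eps_Bi T)^n kappa_{m,n}(tau, D_i)
#'  B_{m,n}(T, tau_i)`, times the flow factor when the model carries one.
#'
#' @param m,n Orders (vectorised, recycled with `tau`).
#' @param tau Lag time(s), s.
#' @param T Bin time, s (scalar or vectorised).
#' @param model A [cpch_model()].
#' @return Factorial cumulant value(s).
#' @export
factorial_cumulant <- function(m, n, tau, T, model) {
  stopifnot(inherits(model, "cpch_model"))
  k <- .check_orders(m, n)
  len <- max(length(k$m), length(tau), length(T))
  m <- rep_len(k$m, len); n <- rep_len(k$n, len)
  tau <- rep_len(tau, len); T <- rep_len(T, len)
  opt <- model$optical
  beta_A <- (opt$r_A / opt$z_A)^2
  beta_B <- (opt$r_B / opt$z_B)^2
  gam <- shape_factor(m, n, opt)
  out <- numeric(len)
  for (sp in model$species) {
    kap <- diffusion_factor(m, n, tau, sp$D, opt)
    B <- binning_Bmn(m, n, T, sp$tau_A, sp$tau_B, beta_A, beta_B)
    g <- sp$N * (sp$eps_A * T)^m * (sp$eps_B * T)^n * gam * kap * B
    if (!is.null(model$flow))
      g <- g * flow_factor(m, n, tau, sp$D, model$flow[1], model$flow[2], opt)
    out <- out + g
  }
  # Poisson background contributes only to the first-order cumulants,
  # scaled from the reference bin to T
  first_A <- m == 1 & n == 0
  first_B <- m == 0 & n == 1
  out[first_A] <- out[first_A] + model$lambda_A * T[first_A] / model$T_ref
  out[first_B] <- out[first_B] + model$lambda_B * T[first_B] / model$T_ref
  out
}

#' Model factorial-cumulant table
#'
#' Evaluates [factorial_cumulant()] on the cross product of a set of orders
#' and a lag grid, returning a table in the same layout as the empirical
#' tables produced by [empirical_moments()].
#'
#' @param model A [cpch_model()].
#' @param tau Lag times, s.
#' @param T Bin time, s (scalar or one per lag).
#' @param orders Two-column matrix (m, n); defaults to all orders with
#'   `1 <= m + n <= 4`.
#' @return A `cumulant_table` data frame with columns m, n, tau, T, value.
#' @export
model_cumulant_table <- function(model, tau, T, orders = default_orders()) {
  T <- rep_len(T, length(tau))
  grid <- expand_orders(orders, tau, T)
  val <- factorial_cumulant(grid$m, grid$n, grid$tau, grid$T, model)
  structure(data.frame(m = grid$m, n = grid$n, tau = grid$tau, T = grid$T,
                       value = val, variance = NA_real_, N_d = NA_real_),
            class = c("cumulant_table", "data.frame"),
            kind = "factorial_cumulant")
}

#' Default moment orders for fitting
#'
#' All bivariate orders (m, n) with `1 <= m + n <= max_order`.
#'
#' @param max_order Maximum combined order (default 4).
#' @return Two-column integer matrix.
#' @export
default_orders <- function(max_order = 4) {
  g <- expand.grid(m = 0:max_order, n = 0:max_order)
  g <- g[g$m + g$n >= 1 & g$m + g$n <= max_order, ]
  as.matrix(g[order(g$m + g$n, g$m), ])
}

expand_orders <- function(orders, tau, T) {
  orders <- as.matrix(orders)
  no <- nrow(orders); nt <- length(tau)
  list(m = rep(orders[, 1], times = nt),
       n = rep(orders[, 2], times = nt),
       tau = rep(tau, each = no),
       T = rep(T, each = no))
}
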