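#' Convert between bivariate moment kinds
#'
#' Converts a complete matrix of bivariate moments of one kind into another:
#' raw moments, factorial moments, cumulants, or factorial cumulants.
#' Raw and factorial moments are linked by Stirling-number transforms per
#' axis; moments and cumulants of either flavour are linked by the bivariate
#' exponential (Bell-polynomial) recursion. All conversions at order (m, n)
#' require every lower order, so the input matrix must be complete.
#'
#' @param mat Numeric matrix indexed `[m + 1, n + 1]` over orders
#'   `0..(nrow-1)` and `0..(ncol-1)`. The (0, 0) entry is ignored on input
#'   (it is 1 for moments and 0 for cumulants).
#' @param from,to One of `"raw"`, `"factorial_moment"`, `"cumulant"`,
#'   `"factorial_cumulant"`.
#' @return Matrix of the same shape holding the target kind.
#' @examples
#' # a Poisson channel has only a first factorial cumulant
#' m <- convert_moments(matrix(c(0, 2, 0, 0), 4, 1), "factorial_cumulant", "raw")
#' @export
convert_moments <- function(mat,
                            from = c("raw", "factorial_moment", "cumulant",
                                     "factorial_cumulant"),
                            to = c("raw", "factorial_moment", "cumulant",
                                   "factorial_cumulant")) {
  from <- match.arg(from); to <- match.arg(to)
  mat <- as.matrix(mat)
  if (from == to) return(mat)
  raw <- switch(from,
    raw = { m <- mat; m[1, 1] <- 1; m },
    factorial_moment = .stirling_apply(mat, stirling2_matrix, one = TRUE),
    cumulant = .moments_from_cumulants(mat),
    factorial_cumulant = .stirling_apply(.moments_from_cumulants(mat),
                                         stirling2_matrix, one = TRUE))
  switch(to,
    raw = raw,
    factorial_moment = .stirling_apply(raw, stirling1_matrix, one = TRUE),
    cumulant = .cumulants_from_moments(raw),
    factorial_cumulant = .cumulants_from_moments(
      .stirling_apply(raw, stirling1_matrix, one = TRUE)))
}

.stirling_apply <- function(mat, maker, one = FALSE) {
  A <- maker(nrow(mat) - 1)
  B <- maker(ncol(mat) - 1)
  out <- A %*% `[<-`(mat, 1, 1, 1) %*% t(B)
  if (one) out[1, 1] <- 1
  out
}

# moment matrix from cumulant matrix (works for raw/cumulant and
# factorial-moment/factorial-cumulant pairs alike)
.moments_from_cumulants <- function(K) {
  mm <- nrow(K) - 1; nn <- ncol(K) - 1
  M <- matrix(0, mm + 1, nn + 1)
  M[1, 1] <- 1
  for (tot in 1:(mm + nn)) for (m in 0:min(mm, tot)) {
    n <- tot - m
    if (n > nn) next
    if (m >= 1) {
      acc <- 0
      for (i in 0:(m - 1)) for (j in 0:n)
        acc <- acc + choose(m - 1, i) * choose(n, j) *
          K[m - i + 1, n - j + 1] * M[i + 1, j + 1]
      M[m + 1, n + 1] <- acc
    } else {
      acc <- 0
      for (j in 0:(n - 1))
        acc <- acc + choose(n - 1, j) * K[1, n - j + 1] * M[1, j + 1]
      M[1, n + 1] <- acc
    }
  }
  M
}

.cumulants_from_moments <- function(M) {
  mm <- nrow(M) - 1; nn <- ncol(M) - 1
  K <- matrix(0, mm + 1, nn + 1)
  for (tot in 1:(mm + nn)) for (m in 0:min(mm, tot)) {
    n <- tot - m
    if (n > nn) next
    if (m >= 1) {
      acc <- 0
      for (i in 0:(m - 1)) for (j in 0:n) {
        if (i == 0 && j == 0) next
        acc <- acc + choose(m - 1, i) * choose(n, j) *
          K[m - i + 1, n - j + 1] * M[i + 1, j + 1]
      }
      K[m + 1, n + 1] <- M[m + 1, n + 1] - acc
    } else {
      acc <- 0
      if (n >= 2) for (j in 1:(n - 1))
        acc <- acc + choose(n - 1, j) * K[1, n - j + 1] * M[1, j + 1]
      K[1, n + 1] <- M[1, n + 1] - acc
    }
  }
  K
}

# Symbolic factorial cumulant (p, r) as a polynomial in raw-moment
# variables "M<i>.<j>" with i <= p, j <= r. Cached per (p, r, kind).
.poly_cache <- new.env(parent = emptyenv())

cumulant_polynomial <- function(p, r, kind = c("factorial_cumulant", "cumulant")) {
  kind <- match.arg(kind)
  key <- paste(kind, p, r, sep = "_")
  if (!is.null(.poly_cache[[key]])) return(.poly_cache[[key]])
  rawvar <- function(i, j) {
    if (i == 0 && j == 0) poly_const(1) else poly_var(sprintf("M%d.%d", i, j))
  }
  # moments of the wanted flavour as polynomials in the raw moments
  if (kind == "factorial_cumulant") {
    s1m <- stirling1_matrix(p); s1n <- stirling1_matrix(r)
    mom <- function(i, j) {
      acc <- poly_const(0)
      for (a in 0:i) for (b in 0:j) {
        c1 <- s1m[i + 1, a + 1] * s1n[j + 1, b + 1]
        if (c1 != 0) acc <- poly_add(acc, poly_scale(rawvar(a, b), c1))
      }
      acc
    }
  } else mom <- rawvar
  Mp <- vector("list", (p + 1) * (r + 1))
  dim(Mp) <- c(p + 1, r + 1)
  for (i in 0:p) for (j in 0:r) Mp[[i + 1, j + 1]] <- mom(i, j)
  Kp <- vector("list", (p + 1) * (r + 1))
  dim(Kp) <- c(p + 1, r + 1)
  Kp[[1, 1]] <- poly_const(0)
  for (tot in 1:(p + r)) for (m in 0:min(p, tot)) {
    n <- tot - m
    if (n > r) next
    if (m >= 1) {
      acc <- poly_const(0)
      for (i in 0:(m - 1)) for (j in 0:n) {
        if (i == 0 && j == 0) next
        cc <- choose(m - 1, i) * choose(n, j)
        acc <- poly_add(acc, poly_scale(poly_mul(Kp[[m - i + 1, n - j + 1]],
                                                 Mp[[i + 1, j + 1]]), cc))
      }
      Kp[[m + 1, n + 1]] <- poly_add(Mp[[m + 1, n + 1]], poly_scale(acc, -1))
    } else {
      acc <- poly_const(0)
      if (n >= 2) for (j in 1:(n - 1)) {
        cc <- choose(n - 1, j)
        acc <- poly_add(acc, poly_scale(poly_mul(Kp[[1, n - j + 1]],
                                                 Mp[[1, j + 1]]), cc))
      }
      Kp[[1, n + 1]] <- poly_add(Mp[[1, n + 1]], poly_scale(acc, -1))
    }
  }
  out <- Kp[[p + 1, r + 1]]
  .poly_cache[[key]] <- out
  out
}

#' Delta-method variance of an empirical (factorial) cumulant
#'
#' First-order (in `1/N_d`) sampling variance of the order-(p, r) cumulant
#' or factorial cumulant estimated from `N_d` count pairs, using the
#' moments-of-moments expansion: the cumulant is written as a closed-form
#' polynomial in the raw moments, its exact partial derivatives are
#' evaluated at the empirical raw moments, and the raw-moment covariances
#' `Cov[M_xy, M_uv] = (M_{x+u, y+v} - M_xy M_uv) / N_d` are contracted with
#' them. Counts in different bin pairs are treated as independent.
#'
#' @param raw Matrix of empirical raw moments indexed `[m + 1, n + 1]`,
#'   complete up to order `(2p, 2r)`.
#' @param p,r Target order.
#' @param N_d Number of data points (bin pairs).
#' @param kind `"factorial_cumulant"` (default) or `"cumulant"`.
#' @return The variance (a scalar).
#' @export
mom_variance <- function(raw, p, r, N_d, kind = "factorial_cumulant") {
  raw <- as.matrix(raw)
  if (N_d <= 0) .stopf("N_d must be positive")
  if (nrow(raw) < 2 * p + 1 || ncol(raw) < 2 * r + 1)
    .stopf("raw moments up to order (2p, 2r) = (%d, %d) are required", 2 * p, 2 * r)
  X <- cumulant_polynomial(p, r, kind)
  vars <- expand.grid(x = 0:p, y = 0:r)
  vars <- vars[vars$x + vars$y >= 1, , drop = FALSE]
  vals <- list()
  for (i in 0:(2 * p)) for (j in 0:(2 * r))
    vals[[sprintf("M%d.%d", i, j)]] <- raw[i + 1, j + 1]
  d <- mapply(function(x, y) {
    poly_eval(poly_deriv(X, sprintf("M%d.%d", x, y)), vals)
  }, vars$x, vars$y)
  v <- 0
  for (a in seq_len(nrow(vars))) for (b in seq_len(nrow(vars))) {
    if (d[a] == 0 || d[b] == 0) next
    x <- vars$x[a]; y <- vars$y[a]; u <- vars$x[b]; vv <- vars$y[b]
    cov <- (raw[x + u + 1, y + vv + 1] -
              raw[x + 1, y + 1] * raw[u + 1, vv + 1]) / N_d
    v <- v + d[a] * d[b] * cov
  }
  v
}

#' Build a cumulant table
#'
#' Internal-facing constructor for the long-format table used throughout:
#' one row per (m, n, tau, T) with a value, its sampling variance and the
#' number of data points.
#' @param df Data frame with columns m, n, tau, T, value, variance, N_d.
#' @param kind Moment kind carried by `value`.
#' @return A `cumulant_table`.
#' @export
cumulant_table <- function(df, kind = "factorial_cumulant") {
  need <- c("m", "n", "tau", "T", "value", "variance", "N_d")
  miss <- setdiff(need, names(df))
  for (x in miss) df[[x]] <- NA_real_
  structure(as.data.frame(df)[need],
            class = c("cumulant_table", "data.frame"), kind = kind)
}

#' @export
print.cumulant_table <- function(x, ...) {
  cat(sprintf("cumulant_table (%s): %d rows, %d lag(s)\n",
              attr(x, "kind"), nrow(x), length(unique(x$tau))))
  NextMethod()
}

#' FCS autocorrelation curve from cPCH cumulants
#'
#' The normalised FCS autocorrelation is recovered from the first-order
#' joint factorial cumulants:
#' `G(tau) = 1 + (K)_{1,1} / ((K)_{1,0} (K)_{0,1})` for `tau > 0`. At
#' `tau = 0` the joint histogram is diagonal and one-dimensional statistics
#' are substituted: `M_{1,1}(0) = (K)_1 + (K)_1^2 + (K)_2`, so
#' `G(0) = ((K)_1 + (K)_1^2 + (K)_2) / (K)_1^2` (the table must then carry
#' the 1D cumulants as orders (1, 0) and (2, 0) at `tau = 0`).
#'
#' Per-point variances, when present in the table, are propagated to `G` by
#' the delta method, neglecting covariances between the cumulants.
#'
#' @param table A `cumulant_table` of factorial cumulants containing orders
#'   (1,0), (0,1) and (1,1) for each positive lag.
#' @return Data frame with columns `tau`, `G`, `var_G` (class `fcs_curve`).
#' @export
fcs_from_cpch <- function(table) {
  stopifnot(inherits(table, "cumulant_table"))
  taus <- sort(unique(table$tau))
  # first-order cumulants are lag-independent; tables that store them only
  # once (marginals_once) provide them for every lag
  k10_all <- table[table$m == 1 & table$n == 0, , drop = FALSE]
  k01_all <- table[table$m == 0 & table$n == 1, , drop = FALSE]
  out <- lapply(taus, function(tt) {
    sub <- table[table$tau == tt, ]
    pick <- function(mm, nn) {
      got <- sub[sub$m == mm & sub$n == nn, , drop = FALSE]
      if (nrow(got)) return(got)
      if (mm == 1 && nn == 0) return(k10_all[1, , drop = FALSE])
      if (mm == 0 && nn == 1) return(k01_all[1, , drop = FALSE])
      got
    }
    if (tt == 0) {
      k1 <- pick(1, 0); k2 <- pick(2, 0)
      if (!nrow(k1) || !nrow(k2)) return(NULL)
      if (k1$value == 0) .stopf("undefined FCS value: zero mean counts")
      G <- (k1$value + k1$value^2 + k2$value) / k1$value^2
      vG <- NA_real_
    } else {
      k10 <- pick(1, 0); k01 <- pick(0, 1); k11 <- pick(1, 1)
      if (!nrow(k10) || !nrow(k01) || !nrow(k11)) return(NULL)
      if (k10$value == 0 || k01$value == 0)
        .stopf("undefined FCS value: zero mean counts")
      amp <- k11$value / (k10$value * k01$value)
      G <- 1 + amp
      vG <- if (all(is.finite(c(k10$variance, k01$variance, k11$variance)))) {
        amp^2 * (k11$variance / k11$value^2 + k10$variance / k10$value^2 +
                   k01$variance / k01$value^2)
      } else NA_real_
    }
    data.frame(tau = tt, G = G, var_G = vG)
  })
  out <- do.call(rbind, out)
  class(out) <- c("fcs_curve", "data.frame")
  out
}

#' One-dimensional factorial cumulants (fluorescence cumulant analysis)
#'
#' The single-channel factorial cumulants used in FCA are the (n, 0) orders
#' of the cPCH factorial cumulants. Given a `cumulant_table` this subsets
#' the table; given a `cpch_model` it evaluates
#' `(K)_n = sum_i N_i (eps_i T)^n gamma_{n,0} B_{n,0}` directly.
#'
#' @param x A `cumulant_table` or a [cpch_model()].
#' @param n Orders to return (default 1:4).
#' @param T Bin time (model route), s.
#' @return A `cumulant_table` with `n == 0` rows only.
#' @export
fca_cumulants <- function(x, n = 1:4, T = NULL) {
  if (inherits(x, "cumulant_table")) {
    out <- x[x$n == 0 & x$m %in% n, ]
    attr(out, "kind") <- attr(x, "kind")
    class(out) <- class(x)
    return(out)
  }
  stopifnot(inherits(x, "cpch_model"))
  if (is.null(T)) T <- x$T_ref
  val <- factorial_cumulant(n, 0, 0, T, x)
  cumulant_table(data.frame(m = n, n = 0, tau = 0, T = T, value = val,
                            variance = NA_real_, N_d = NA_real_))
}
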