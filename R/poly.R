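# Minimal multivariate polynomial arithmetic used to express factorial
# cumulants as closed-form polynomials in the raw moments, so that the
# delta-method variance can use exact partial derivatives.
#
# A polynomial is a named numeric vector: names are canonical monomial keys
# ("var:pow;var:pow" with vars sorted; "" is the constant monomial).

.mono_key <- function(pow) {
  pow <- pow[pow > 0]
  if (!length(pow)) return("")
  pow <- pow[order(names(pow))]
  paste(names(pow), pow, sep = ":", collapse = ";")
}

.mono_parse <- function(key) {
  if (identical(key, "")) return(setNames(integer(0), character(0)))
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  setNames(as.integer(vapply(parts, `[`, "", 2L)),
           vapply(parts, `[`, "", 1L))
}

poly_const <- function(x) if (x == 0) setNames(numeric(0), character(0)) else setNames(x, "")

poly_var <- function(name) setNames(1, paste0(name, ":1"))

poly_add <- function(p, q) {
  keys <- union(names(p), names(q))
  out <- setNames(numeric(length(keys)), keys)
  out[names(p)] <- p
  out[names(q)] <- out[names(q)] + q
  out[out != 0]
}

poly_scale <- function(p, a) {
  if (a == 0) return(poly_const(0))
  p * a
}

poly_mul <- function(p, q) {
  if (!length(p) || !length(q)) return(poly_const(0))
  acc <- list()
  for (i in seq_along(p)) {
    pi_pow <- .mono_parse(names(p)[i])
    for (j in seq_along(q)) {
      qj_pow <- .mono_parse(names(q)[j])
      vars <- union(names(pi_pow), names(qj_pow))
      pow <- setNames(integer(length(vars)), vars)
      pow[names(pi_pow)] <- pi_pow
      pow[names(qj_pow)] <- pow[names(qj_pow)] + qj_pow
      key <- .mono_key(pow)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p[[i]] * q[[j]]
    }
  }
  out <- unlist(acc)
  if (is.null(out)) poly_const(0) else out[out != 0]
}

poly_deriv <- function(p, var) {
  if (!length(p)) return(poly_const(0))
  acc <- list()
  for (i in seq_along(p)) {
    pow <- .mono_parse(names(p)[i])
    k <- unname(pow[var])
    if (is.na(k) || k == 0) next
    coef <- p[[i]] * k
    pow[var] <- k - 1L
    key <- .mono_key(pow)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + coef
  }
  out <- unlist(acc)
  if (is.null(out)) poly_const(0) else out[out != 0]
}

poly_eval <- function(p, values) {
  if (!length(p)) return(0)
  tot <- 0
  for (i in seq_along(p)) {
    pow <- .mono_parse(names(p)[i])
    term <- p[[i]]
    for (v in names(pow)) term <- term * values[[v]]^pow[[v]]
    tot <- tot + term
  }
  tot
}

# Stirling numbers -----------------------------------------------------------

stirling2_matrix <- function(nmax) {
  S <- matrix(0, nmax + 1, nmax + 1)
  S[1, 1] <- 1
  if (nmax >= 1) for (nn in 1:nmax) for (kk in 1:nn)
    S[nn + 1, kk + 1] <- kk * S[nn, kk + 1] + S[nn, kk]
  S
}

stirling1_matrix <- function(nmax) {
  # signed Stirling numbers of the first kind
  S <- matrix(0, nmax + 1, nmax + 1)
  S[1, 1] <- 1
  if (nmax >= 1) for (nn in 1:nmax) for (kk in 1:nn)
    S[nn + 1, kk + 1] <- S[nn, kk] - (nn - 1) * S[nn, kk + 1]
  S
}
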