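#' Raster-scan geometry
#'
#' @param delta_x,delta_y Pixel size, micrometres.
#' @param dwell Pixel dwell time, s.
#' @param line_retrace Line retrace time, s.
#' @param frame_retrace Frame retrace time, s.
#' @param pixels_per_line Pixels per scan line (the fast axis).
#' @param lines_per_frame Lines per frame.
#' @return Object of class `scan_geometry`.
#' @export
scan_geometry <- function(delta_x, delta_y = delta_x, dwell,
                          line_retrace = 0, frame_retrace = 0,
                          pixels_per_line, lines_per_frame = pixels_per_line) {
  if (any(c(delta_x, delta_y, dwell) <= 0) ||
      any(c(line_retrace, frame_retrace) < 0) ||
      pixels_per_line < 1 || lines_per_frame < 1)
    .stopf("invalid scan geometry")
  structure(list(delta_x = delta_x, delta_y = delta_y, dwell = dwell,
                 line_retrace = line_retrace, frame_retrace = frame_retrace,
                 pixels_per_line = as.integer(pixels_per_line),
                 lines_per_frame = as.integer(lines_per_frame)),
            class = "scan_geometry")
}

#' Lag time of a pixel offset
#'
#' Time for a raster-scanning laser to travel from one pixel to another
#' `d_x` pixels along the line and `d_y` lines down:
#' `tau = dwell * (d_x + pixels_per_line * d_y) + line_retrace * d_y`.
#' Only forward (causal) offsets with non-negative lag are allowed.
#'
#' @param d_x,d_y Pixel offsets (vectorised; `|d_x| < pixels_per_line`).
#' @param geom A [scan_geometry()].
#' @return Lag(s) in seconds.
#' @examples
#' g <- scan_geometry(0.0117, dwell = 10e-6, line_retrace = 1e-3,
#'                    pixels_per_line = 512)
#' offset_to_tau(3, 2, g)  # 12.27 ms
#' @export
offset_to_tau <- function(d_x, d_y, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (any(abs(d_x) >= geom$pixels_per_line))
    .stopf("|d_x| must be smaller than pixels_per_line")
  tau <- geom$dwell * (d_x + geom$pixels_per_line * d_y) +
    geom$line_retrace * d_y
  if (any(tau < 0)) .stopf("backward offsets (negative lag) are not allowed")
  tau
}

#' Model factorial cumulants at a pixel offset
#'
#' Spatial cPCH treats the scanner displacement between two pixels as a
#' flow: the lag follows from [offset_to_tau()] and the flow decay uses the
#' physical displacement `(d_x * delta_x, d_y * delta_y)`. At zero offset
#' this reduces to the temporal cumulant at `tau = 0`.
#'
#' @param m,n Orders (vectorised together).
#' @param d_x,d_y Pixel offset (scalars).
#' @param model A [cpch_model()].
#' @param geom A [scan_geometry()].
#' @param T Bin time; defaults to the pixel dwell.
#' @return Factorial cumulant value(s).
#' @export
spatial_cumulants_model <- function(m, n, d_x, d_y, model, geom,
                                    T = geom$dwell) {
  stopifnot(inherits(model, "cpch_model"), inherits(geom, "scan_geometry"))
  tau <- offset_to_tau(d_x, d_y, geom)
  m2 <- model
  if (tau > 0) {
    m2$flow <- c(d_x * geom$delta_x, d_y * geom$delta_y) / tau
  } else {
    m2$flow <- NULL
  }
  factorial_cumulant(m, n, tau, T, m2)
}

#' Empirical cPCH histogram of an image stack at a pixel offset
#'
#' Pairs the photon counts of every pixel with the pixel `(d_x, d_y)` away
#' in the same frame (pairs crossing frame edges are discarded) and tallies
#' the joint histogram, accumulating across frames.
#'
#' @param stack Integer array `[pixels, lines, frames]` of photon counts.
#' @param d_x,d_y Forward pixel offset (`d_y >= 0`).
#' @param geom Optional [scan_geometry()] used to stamp `tau` metadata.
#' @return A `cpch_hist`.
#' @export
build_spatial_hist <- function(stack, d_x, d_y, geom = NULL) {
  p <- .spatial_pairs(stack, d_x, d_y)
  tau <- if (!is.null(geom)) offset_to_tau(d_x, d_y, geom) else NA_real_
  T <- if (!is.null(geom)) geom$dwell else NA_real_
  h <- build_cpch_hist(p$a, 0L, y = p$b, tau = tau, T = T)
  h$d_x <- d_x; h$d_y <- d_y
  h
}

.spatial_pairs <- function(stack, d_x, d_y) {
  d <- dim(stack)
  if (length(d) == 2) { dim(stack) <- c(d, 1); d <- dim(stack) }
  if (d_y < 0) .stopf("only forward offsets (d_y >= 0) are supported")
  if (abs(d_x) >= d[1] || d_y >= d[2]) .stopf("offset larger than the image")
  xi <- if (d_x >= 0) 1:(d[1] - d_x) else (1 - d_x):d[1]
  yi <- 1:(d[2] - d_y)
  a <- stack[xi, yi, , drop = FALSE]
  b <- stack[xi + d_x, yi + d_y, , drop = FALSE]
  list(a = as.vector(a), b = as.vector(b))
}

#' Empirical spatial factorial cumulants over a set of pixel offsets
#'
#' For each offset, pairs pixels within frames, accumulates raw moments of
#' the count pairs and converts to factorial cumulants. The returned table
#' carries `d_x`, `d_y` columns alongside the lag implied by the scan
#' geometry.
#'
#' Variances: neighbouring pixels are strongly correlated (the beam waist
#' spans many pixels), so the independent-pair moments-of-moments formula
#' badly underestimates spatial sampling variances. When the stack holds at
#' least three frames (default), frames — separated by a full scan plus
#' retrace, far longer than any diffusion time — are treated as independent
#' replicates and each cumulant's variance is the across-frame variance of
#' its per-frame estimate divided by the number of frames. With fewer
#' frames the delta-method variance is used and flagged as approximate.
#'
#' @param stack Integer array `[pixels, lines, frames]`.
#' @param offsets Two-column matrix of (d_x, d_y) offsets.
#' @param geom A [scan_geometry()].
#' @param orders Orders matrix as in [empirical_cumulants()].
#' @param variances Attach variances (default TRUE).
#' @param frame_variance Use across-frame replicate variances (default).
#' @param marginals_once Keep the offset-independent pure-channel orders
#'   only at the first offset (default TRUE).
#' @return A `cumulant_table` with extra columns `d_x`, `d_y`.
#' @export
spatial_cumulant_table <- function(stack, offsets, geom,
                                   orders = default_orders(),
                                   variances = TRUE, frame_variance = TRUE,
                                   marginals_once = TRUE) {
  stopifnot(inherits(geom, "scan_geometry"))
  offsets <- as.matrix(offsets)
  d <- dim(stack)
  if (length(d) == 2) { dim(stack) <- c(d, 1); d <- dim(stack) }
  nf <- d[3]
  one_pass <- function(sub, with_var) {
    out <- vector("list", nrow(offsets))
    for (i in seq_len(nrow(offsets))) {
      p <- .spatial_pairs(sub, offsets[i, 1], offsets[i, 2])
      tab <- empirical_cumulants(p$a, geom$dwell, 0L, y = p$b,
                                 orders = orders, variances = with_var,
                                 acf_correction = FALSE)
      tab$tau <- offset_to_tau(offsets[i, 1], offsets[i, 2], geom)
      tab$d_x <- offsets[i, 1]
      tab$d_y <- offsets[i, 2]
      out[[i]] <- tab
    }
    do.call(rbind, out)
  }
  if (variances && frame_variance && nf >= 3) {
    tabs <- lapply(seq_len(nf), function(f)
      one_pass(stack[, , f, drop = FALSE], FALSE))
    vals <- vapply(tabs, function(t) t$value, tabs[[1]]$value)
    res <- tabs[[1]]
    res$value <- rowMeans(vals)
    res$variance <- apply(vals, 1, stats::var) / nf
    res$N_d <- res$N_d * nf
  } else {
    if (variances && frame_variance)
      .warnf("fewer than 3 frames: falling back to independent-pair variances")
    res <- one_pass(stack, variances)
  }
  if (marginals_once) {
    first <- res$d_x == offsets[1, 1] & res$d_y == offsets[1, 2]
    res <- res[res$m >= 1 & res$n >= 1 | first, ]
  }
  structure(res, class = c("cumulant_table", "data.frame"),
            kind = "factorial_cumulant")
}
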