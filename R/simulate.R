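#' Simulate a photon-count trace by Brownian dynamics
#'
#' Places the model's species uniformly in a periodic box (absolute copy
#' numbers are the occupancies scaled by the box-to-observation-volume
#' ratio), then at every sampling step `dt` emits Poisson photons per
#' molecule and channel with mean given by the 3D Gaussian intensity
#' profile at the molecule's position, and updates positions with Gaussian
#' increments of per-axis variance `2 D dt`, wrapping at the boundaries.
#' Photons are emitted from the positions current at the start of each
#' step (emit-then-move convention). Molecules provably too far from the
#' observation region to emit are advanced by exact block Brownian
#' increments, which leaves the photon statistics unchanged.
#'
#' Poisson background counts (from the model's `lambda_A`, `lambda_B`) are
#' added per bin using R's RNG stream.
#'
#' @param model A [cpch_model()].
#' @param duration Trace duration, s.
#' @param dt Sampling (bin) time, s; should be well below the shortest
#'   diffusion time (a warning is issued above `tau_d / 5`).
#' @param seed Integer seed for the simulator's own RNG stream.
#' @param box Box dimensions `c(x, y, z)` in um, centred on the focus.
#' @return Object of class `cpch_trace`: integer vectors `A`, `B` of counts
#'   per bin, plus `dt`, `duration`, `n_mol` and the effective occupancies.
#' @export
simulate_trace <- function(model, duration, dt, seed = 1, box = c(4, 4, 8)) {
  stopifnot(inherits(model, "cpch_model"))
  if (duration <= 0 || dt <= 0) .stopf("duration and dt must be positive")
  opt <- model$optical
  if (any(box[1:2] < 6 * max(opt$r_A, opt$r_B)) || box[3] < 6 * max(opt$z_A, opt$z_B))
    .warnf("box is not large compared with the observation volume")
  taus <- vapply(model$species, `[[`, 0, "tau_A")
  if (dt > min(taus) / 5)
    .warnf("dt = %g s is not small compared with tau_d = %g s", dt, min(taus))
  steps <- round(duration / dt)
  Vab <- observation_volume(opt)
  Vbox <- prod(box)
  n_mol <- vapply(model$species, function(sp) as.integer(round(sp$N * Vbox / Vab)), 1L)
  counts <- .sim_trace_cpp(n_mol,
                           vapply(model$species, `[[`, 0, "D"),
                           vapply(model$species, `[[`, 0, "eps_A") * dt,
                           vapply(model$species, `[[`, 0, "eps_B") * dt,
                           opt$r_A, opt$z_A, opt$r_B, opt$z_B,
                           box, dt, steps, as.double(seed))
  lamA <- model$lambda_A * dt / model$T_ref
  lamB <- model$lambda_B * dt / model$T_ref
  A <- counts[, 1]; B <- counts[, 2]
  if (lamA > 0) A <- A + rpois(steps, lamA)
  if (lamB > 0) B <- B + rpois(steps, lamB)
  structure(list(A = A, B = B, dt = dt, duration = steps * dt,
                 n_mol = n_mol, N_eff = n_mol * Vab / Vbox,
                 box = box, seed = seed, model = model),
            class = "cpch_trace")
}

#' @export
print.cpch_trace <- function(x, ...) {
  cat(sprintf("cpch_trace: %g s at dt=%g s (%d bins), %s molecules, mean A=%.4g counts/bin\n",
              x$duration, x$dt, length(x$A),
              paste(x$n_mol, collapse = "+"), mean(x$A)))
  invisible(x)
}

#' Simulate a raster-scanned image stack
#'
#' Extends [simulate_trace()] to a scanning acquisition: for each pixel,
#' photons are counted from all molecules with the point-spread function
#' centred at the pixel, then molecule positions are updated over one pixel
#' dwell. Between lines and frames, positions are updated over the retrace
#' times in dwell-sized steps (with boundary wrapping at every step). The
#' simulation box spans four times the scanned region laterally and 8 um
#' axially, with the scan plane through the box centre.
#'
#' Imaging uses channel A only.
#'
#' @param model A [cpch_model()].
#' @param geom A [scan_geometry()].
#' @param frames Number of frames.
#' @param seed Integer seed.
#' @param box Optional box override, um.
#' @return Object of class `cpch_stack` with integer array `counts`
#'   `[pixels, lines, frames]` and metadata.
#' @export
simulate_image_stack <- function(model, geom, frames, seed = 1, box = NULL) {
  stopifnot(inherits(model, "cpch_model"), inherits(geom, "scan_geometry"))
  opt <- model$optical
  X <- geom$pixels_per_line * geom$delta_x
  Y <- geom$lines_per_frame * geom$delta_y
  if (is.null(box)) box <- c(4 * X, 4 * Y, 8)
  if (X > box[1] || Y > box[2]) .stopf("image larger than the box footprint")
  Vab <- observation_volume(opt)
  n_mol <- vapply(model$species, function(sp)
    as.integer(round(sp$N * prod(box) / Vab)), 1L)
  rl <- as.integer(round(geom$line_retrace / geom$dwell))
  rf <- as.integer(round(geom$frame_retrace / geom$dwell))
  counts <- .sim_image_cpp(n_mol,
                           vapply(model$species, `[[`, 0, "D"),
                           vapply(model$species, `[[`, 0, "eps_A") * geom$dwell,
                           opt$r_A, opt$z_A, box,
                           geom$pixels_per_line, geom$lines_per_frame,
                           as.integer(frames),
                           geom$delta_x, geom$delta_y, geom$dwell,
                           rl, rf, as.double(seed))
  lam <- model$lambda_A * geom$dwell / model$T_ref
  if (lam > 0) counts <- counts + array(rpois(length(counts), lam), dim(counts))
  structure(list(counts = counts, geom = geom, frames = frames,
                 n_mol = n_mol, N_eff = n_mol * Vab / prod(box),
                 box = box, seed = seed, model = model),
            class = "cpch_stack")
}

#' @export
print.cpch_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("cpch_stack: %d x %d x %d frames, %s molecules, mean %.4g counts/pixel\n",
              d[1], d[2], d[3], paste(x$n_mol, collapse = "+"),
              mean(x$counts)))
  invisible(x)
}

#' Convert a binned trace to synthetic photon arrival times
#'
#' Distributes each bin's photons uniformly within the bin at the detector
#' sampling resolution. Adequate whenever analyses only use bin-level
#' counts. Uses R's RNG stream.
#'
#' @param counts Counts per bin.
#' @param dt Bin time, s.
#' @param sampling_time Detector resolution, s (default 50 ns).
#' @return Sorted arrival times in seconds.
#' @export
trace_to_arrivals <- function(counts, dt, sampling_time = 50e-9) {
  ticks_per_bin <- round(dt / sampling_time)
  idx <- rep(seq_along(counts) - 1, counts)
  t_s <- idx * ticks_per_bin + sample.int(ticks_per_bin, length(idx), replace = TRUE)
  sort(t_s) * sampling_time
}

# reference beam waist used by the simulation presets (um): with
# tau_d = 175.7 us this gives D = 100 um^2/s
.r0 <- 0.2651

#' Simulation presets with known ground truth
#'
#' Named single- and two-species study conditions used throughout the
#' package's validation, with the optical geometry `r = 0.2651 um`.
#'
#' @param name Preset name: `"table1_single"`, `"fig4a_two_species"`,
#'   `"fig4b_brightness_only"`, `"dim_pair"`, `"table2_spatial"`,
#'   `"fig3b_mixture"`, `"ligand_receptor"`.
#' @return List with elements `model`, `kind` ("trace" or "image"), and
#'   either `dt`/`duration` or `geom`/`frames` defaults.
#' @export
cpch_preset <- function(name) {
  r <- .r0
  opt_s <- function(s) optical_config(r, s * r)
  g_img <- scan_geometry(0.0117, dwell = 1e-5, line_retrace = 1e-3,
                         frame_retrace = 5e-3, pixels_per_line = 256)
  switch(name,
    table1_single = list(
      model = cpch_model(opt_s(1.928),
                         species_params(N = 1, eps_A = 24448, tau_d = 175.7e-6),
                         T_ref = 1e-5),
      kind = "trace", dt = 1e-5, duration = 60),
    fig4a_two_species = list(
      model = cpch_model(opt_s(1.928), list(
        species_params(N = 8, eps_A = 48895, tau_d = 87.85e-6),
        species_params(N = 2, eps_A = 146686, tau_d = 439.24e-6)),
        T_ref = 1e-5),
      kind = "trace", dt = 1e-5, duration = 30),
    fig4b_brightness_only = list(
      model = cpch_model(opt_s(1.928), list(
        species_params(N = 8, eps_A = 48895, tau_d = 21.96e-6),
        species_params(N = 5, eps_A = 146686, tau_d = 25.16e-6)),
        T_ref = 1e-5),
      kind = "trace", dt = 2e-6, duration = 30),
    dim_pair = list(
      model = cpch_model(opt_s(1.928), list(
        species_params(N = 0.213, eps_A = 17780, tau_d = 43.92e-6),
        species_params(N = 0.213, eps_A = 35560, tau_d = 175.7e-6)),
        T_ref = 3.2e-6),
      kind = "trace", dt = 3.2e-6, duration = 30),
    table2_spatial = list(
      model = cpch_model(opt_s(1.93),
                         species_params(N = 0.6, eps_A = 1.1 / 1e-5, D = 100),
                         T_ref = 1e-5),
      kind = "image", geom = g_img, frames = 5),
    fig3b_mixture = list(
      model = cpch_model(opt_s(1.93), list(
        species_params(N = 1.2, eps_A = 31181, D = 0.1),
        species_params(N = 0.6, eps_A = 95452, D = 200)),
        T_ref = 1e-5),
      kind = "image", geom = g_img, frames = 5),
    ligand_receptor = list(
      # fluorescent ligand L, singly bound receptor R1 (same brightness as
      # L), doubly bound receptor R11 (twice as bright); receptors diffuse
      # much slower than the ligand. Binding equilibrium itself is not
      # simulated: concentrations are inputs.
      model = cpch_model(opt_s(1.93), list(
        species_params(N = 0.5, eps_A = 30000, D = 100),
        species_params(N = 0.2, eps_A = 30000, D = 5),
        species_params(N = 0.1, eps_A = 60000, D = 5)),
        T_ref = 1e-5),
      kind = "image",
      geom = scan_geometry(4 / 512, dwell = 1e-5, line_retrace = 1e-3,
                           frame_retrace = 50e-3, pixels_per_line = 512),
      frames = 1),
    .stopf("unknown preset '%s'", name))
}

#' Write a simulated fixture to disk
#'
#' Simulates a preset and writes plain-text artifacts: the counts (CSV) and
#' a ground-truth JSON holding the model, geometry and seed. The same seed
#' yields byte-identical outputs.
#'
#' @param preset Preset name, see [cpch_preset()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param duration,frames Optional overrides of the preset defaults.
#' @return Invisibly, the list of written paths.
#' @export
make_fixture <- function(preset, seed = 1, dir = ".", duration = NULL,
                         frames = NULL) {
  p <- cpch_preset(preset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, preset)
  truth <- list(preset = preset, seed = seed,
                model = .model_to_list(p$model))
  if (p$kind == "trace") {
    if (is.null(duration)) duration <- p$duration
    tr <- simulate_trace(p$model, duration, p$dt, seed = seed)
    counts_path <- paste0(base, "_counts.csv")
    write.csv(data.frame(A = tr$A, B = tr$B), counts_path, row.names = FALSE)
    truth$dt <- p$dt; truth$duration <- duration; truth$n_mol <- tr$n_mol
  } else {
    if (is.null(frames)) frames <- p$frames
    st <- simulate_image_stack(p$model, p$geom, frames, seed = seed)
    counts_path <- paste0(base, "_stack.csv")
    d <- dim(st$counts)
    write.csv(data.frame(pixel = rep(seq_len(d[1]), times = d[2] * d[3]),
                         line = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                         frame = rep(seq_len(d[3]), each = d[1] * d[2]),
                         counts = as.vector(st$counts)),
              counts_path, row.names = FALSE)
    truth$geom <- unclass(p$geom); truth$frames <- frames; truth$n_mol <- st$n_mol
  }
  truth_path <- paste0(base, "_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(counts = counts_path, truth = truth_path))
}
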