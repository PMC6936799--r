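# Model/config serialisation and table IO. Configs are JSON with explicit
# unit strings per section to avoid the counts-per-bin / counts-per-second
# ambiguity that brightness parameters invite.

.model_to_list <- function(model) {
  list(optical = list(r_A = model$optical$r_A, z_A = model$optical$z_A,
                      r_B = model$optical$r_B, z_B = model$optical$z_B,
                      unit = "um"),
       species = lapply(model$species, function(sp)
         list(N = sp$N, eps_A = sp$eps_A, eps_B = sp$eps_B,
              eps_unit = "counts_per_s", D = sp$D, D_unit = "um2_per_s")),
       background = list(lambda_A = model$lambda_A, lambda_B = model$lambda_B,
                         unit = "counts_per_bin"),
       T_ref = model$T_ref, T_ref_unit = "s",
       flow = if (is.null(model$flow)) NULL else
         list(v_x = model$flow[1], v_y = model$flow[2], unit = "um_per_s"))
}

#' Write a cPCH model configuration to JSON
#'
#' @param model A [cpch_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cpch_config <- function(model, path) {
  stopifnot(inherits(model, "cpch_model"))
  jsonlite::write_json(.model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a cPCH model configuration from JSON
#'
#' Expects sections `optical` (um), `species` (brightness in counts/s or
#' counts/bin per its `eps_unit`, diffusion as `D` in um^2/s or `tau_d` in
#' s), `background` (counts per reference bin) and `T_ref` (s), plus an
#' optional `flow` (um/s).
#'
#' @param path JSON file.
#' @return A [cpch_model()].
#' @export
read_cpch_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  opt <- optical_config(cfg$optical$r_A, cfg$optical$z_A,
                        cfg$optical$r_B %||% cfg$optical$r_A,
                        cfg$optical$z_B %||% cfg$optical$z_A)
  sp <- lapply(cfg$species, function(s)
    species_params(N = s$N, eps_A = s$eps_A, eps_B = s$eps_B %||% s$eps_A,
                   D = s$D %||% NULL, tau_d = s$tau_d %||% NULL,
                   eps_unit = s$eps_unit %||% "counts_per_s"))
  flow <- if (!is.null(cfg$flow)) c(cfg$flow$v_x, cfg$flow$v_y) else NULL
  cpch_model(opt, sp, T_ref = cfg$T_ref,
             lambda_A = cfg$background$lambda_A %||% 0,
             lambda_B = cfg$background$lambda_B %||% 0,
             flow = flow)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cumulant table as CSV
#'
#' @param tab A `cumulant_table`.
#' @param path CSV file.
#' @return `path` (write) or the table (read).
#' @export
write_cumulant_table <- function(tab, path) {
  stopifnot(inherits(tab, "cumulant_table"))
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cumulant_table
#' @export
read_cumulant_table <- function(path) {
  df <- utils::read.csv(path)
  out <- cumulant_table(df)
  extra <- setdiff(names(df), names(out))
  for (e in extra) out[[e]] <- df[[e]]
  out
}

#' Write / read a joint PMF as CSV
#'
#' Long-format CSV with columns `n_x`, `n_y`, `p` and the lag/bin metadata
#' repeated per row; cells with zero probability are omitted.
#'
#' @param pmf A `joint_pmf`.
#' @param path CSV file.
#' @return `path` (write) or a `joint_pmf` (read).
#' @export
write_joint_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "joint_pmf"))
  v <- pmf$values
  idx <- which(v > 0, arr.ind = TRUE)
  df <- data.frame(n_x = idx[, 1] - 1L, n_y = idx[, 2] - 1L, p = v[idx],
                   tau = pmf$tau, T = pmf$T)
  write.csv(df[order(df$n_x, df$n_y), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_joint_pmf
#' @export
read_joint_pmf <- function(path) {
  df <- utils::read.csv(path)
  v <- matrix(0, max(df$n_x) + 1L, max(df$n_y) + 1L)
  v[cbind(df$n_x + 1L, df$n_y + 1L)] <- df$p
  joint_pmf(v, df$tau[1], df$T[1], "restored")
}

#' Write a run manifest
#'
#' Records package version, R version, seed and free-form run parameters as
#' JSON next to run outputs, for reproducibility.
#'
#' @param path Output JSON file.
#' @param ... Named run parameters.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  jsonlite::write_json(
    list(package = "cpch",
         version = as.character(utils::packageVersion("cpch")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC"),
         params = list(...)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
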