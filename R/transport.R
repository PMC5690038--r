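# R front end of the Monte Carlo transport kernel.

GY_PER_MEV_PER_G <- 1.602176634e-10

#' Run the Monte Carlo dose simulation
#'
#' Samples source particles from the combined fluence configuration (cost is
#' therefore independent of the number of shots), transports photons through
#' the voxel phantom with Woodcock tracking, and either deposits energy
#' analogously via straight-line CSDA electrons (`mode = "edep"`, full dose
#' grid) or scores a track-length collision-kerma estimate in a small
#' central region (`mode = "kerma"`, point-dose/output-factor estimates).
#'
#' Doses are reported in "MC units": Gy per history multiplied by the
#' configuration's total fluence-time weight, so results are linear in shot
#' times and source strengths. [calibration_factor()] converts to absolute
#' Gy. Runs are deterministic for a fixed (seed, batches) partition.
#'
#' @param config A `gk_fluence_config` from [build_shot_fluence()].
#' @param phantom A `gk_phantom`.
#' @param spectrum A `gk_spectrum`.
#' @param n_histories Number of primary histories (>= batches).
#' @param seed Integer seed.
#' @param batches Number of independent history batches for the variance
#'   estimate (>= 2).
#' @param mode `"edep"` or `"kerma"`.
#' @param region_center,region_half_mm Kerma scoring box centre and
#'   half-width in mm (default: one voxel at the origin).
#' @param cutoffs Absorption cutoffs in MeV: photon 0.05, electron 0.2.
#' @param brems Sample crude bremsstrahlung from fast electrons (off by
#'   default; its dosimetric effect in water at Co-60 energies is small).
#' @param xsec,csda Cross-section and range tables.
#' @return For `"edep"`: a `gk_dose_grid` (fields `dose`, `relerr`, `voxel`,
#'   `origin`, `n_histories`, `total_weight`, `accounting`). For `"kerma"`:
#'   a `gk_point_dose` (fields `value`, `se`, `relerr`, `batch_means`).
#' @export
run_simulation <- function(config, phantom, spectrum = default_spectrum(),
                           n_histories, seed, batches = 10,
                           mode = c("edep", "kerma"),
                           region_center = c(0, 0, 0), region_half_mm = 0.5,
                           cutoffs = c(photon = 0.05, electron = 0.2),
                           brems = FALSE,
                           xsec = water_xsec_table(),
                           csda = water_csda_table()) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "gk_fluence_config"),
            inherits(phantom, "gk_phantom"))
  if (n_histories <= 0) stop("zero histories requested: nothing to simulate")
  if (batches < 2 || n_histories < batches)
    stop("need n_histories >= batches >= 2")
  if (config$total_weight <= 0) stop("zero-mass fluence")
  if (sum(phantom$density) <= 0 && mode == "kerma")
    warning("phantom contains no material; kerma region is in vacuum")

  opts <- list(n_histories = as.double(n_histories),
               batches = as.integer(batches), seed = as.double(seed),
               mode = mode, e_cut_photon = cutoffs[["photon"]],
               e_cut_electron = cutoffs[["electron"]], brems = brems,
               region_lo = region_center - region_half_mm,
               region_hi = region_center + region_half_mm)
  ph <- list(density = as.numeric(phantom$density),
             dims = as.integer(dim(phantom$density)),
             voxel = phantom$voxel, origin = phantom$origin)
  res <- cpp_run_transport(config$maps, config$instances,
                           spectrum_for_kernel(spectrum),
                           xsec_for_kernel(xsec, csda), ph, opts)
  W <- config$total_weight
  acct <- list(emitted_MeV = res$emitted, deposited_MeV = res$deposited,
               escaped_MeV = res$escaped)
  if (mode == "kerma") {
    v <- res$value * W * GY_PER_MEV_PER_G
    se <- res$se * W * GY_PER_MEV_PER_G
    structure(list(value = v, se = se,
                   relerr = if (v > 0) se / v else Inf,
                   batch_means = res$batch_means * W * GY_PER_MEV_PER_G,
                   n_histories = n_histories, total_weight = W,
                   accounting = acct), class = "gk_point_dose")
  } else {
    mass_g <- phantom$density * (phantom$voxel / 10)^3
    dose <- array(0, dim = dim(mass_g))
    pos <- mass_g > 0
    dose[pos] <- res$energy[pos] / mass_g[pos] * W * GY_PER_MEV_PER_G
    structure(list(dose = dose, relerr = res$relerr, voxel = phantom$voxel,
                   origin = phantom$origin, n_histories = n_histories,
                   total_weight = W, accounting = acct,
                   seed = seed, batches = batches), class = "gk_dose_grid")
  }
}

#' @export
print.gk_dose_grid <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf(
    "<gk_dose_grid> %d x %d x %d voxels at %.3g mm, %.3g histories\n",
    d[1], d[2], d[3], x$voxel, x$n_histories))
  cat(sprintf("  max dose %.4g (MC units), uncertainty summary %.2f%%\n",
              max(x$dose), 100 * uncertainty_summary(x)))
  invisible(x)
}

#' @export
print.gk_point_dose <- function(x, ...) {
  cat(sprintf("<gk_point_dose> %.5g +/- %.2g (MC units, %.2f%% rel)\n",
              x$value, x$se, 100 * x$relerr))
  invisible(x)
}

#' Statistical uncertainty summary of a dose grid
#'
#' The maximum relative standard error over voxels whose dose is at least
#' half of the maximum dose.
#'
#' @param grid A `gk_dose_grid`.
#' @param level Dose threshold as a fraction of the maximum (default 0.5).
#' @return Maximum relative error (fraction).
#' @export
uncertainty_summary <- function(grid, level = 0.5) {
  mx <- max(grid$dose)
  if (mx <= 0) return(NA_real_)
  sel <- grid$dose >= level * mx
  max(grid$relerr[sel])
}

#' Dose at the voxel containing a point
#'
#' @param grid A `gk_dose_grid`.
#' @param point xyz in mm.
#' @return list(value, relerr).
#' @export
dose_at <- function(grid, point = c(0, 0, 0)) {
  idx <- round((point - grid$origin) / grid$voxel) + 1
  d <- dim(grid$dose)
  if (any(idx < 1 | idx > d)) stop("point outside the dose grid")
  list(value = grid$dose[idx[1], idx[2], idx[3]],
       relerr = grid$relerr[idx[1], idx[2], idx[3]])
}

#' Export / import a dose grid (JSON header + flat binary arrays)
#'
#' Writes `<path>.json` (shape, spacing mm, origin mm, units, history count)
#' plus `<path>.dose.bin` and `<path>.err.bin` (little-endian doubles in
#' column-major order).
#'
#' @param grid A `gk_dose_grid`.
#' @param path Base path (no extension).
#' @return [read_dose_grid()] returns the `gk_dose_grid`.
#' @export
write_dose_grid <- function(grid, path) {
  hdr <- list(shape = dim(grid$dose), voxel_mm = grid$voxel,
              origin_mm = grid$origin, units = "Gy (MC units)",
              n_histories = grid$n_histories,
              total_weight = grid$total_weight)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".dose.bin"), "wb")
  writeBin(as.numeric(grid$dose), con, size = 8, endian = "little")
  close(con)
  con <- file(paste0(path, ".err.bin"), "wb")
  writeBin(as.numeric(grid$relerr), con, size = 8, endian = "little")
  close(con)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  hdr <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- prod(hdr$shape)
  dose <- readBin(paste0(path, ".dose.bin"), "numeric", n = n, size = 8,
                  endian = "little")
  err <- readBin(paste0(path, ".err.bin"), "numeric", n = n, size = 8,
                 endian = "little")
  structure(list(dose = array(dose, hdr$shape),
                 relerr = array(err, hdr$shape), voxel = hdr$voxel_mm,
                 origin = hdr$origin_mm, n_histories = hdr$n_histories,
                 total_weight = hdr$total_weight),
            class = "gk_dose_grid")
}
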