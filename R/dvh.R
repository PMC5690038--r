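# Dose profiles, cumulative dose-volume histograms, Dxx and coverage.

#' Extract a 1D dose profile through a point
#'
#' Returns the nearest-voxel line of doses along one axis, normalised to the
#' profile value at the given point.
#'
#' @param grid A `gk_dose_grid`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param point Profile anchor in mm (must lie inside the grid).
#' @return data.frame with `position_mm`, `dose`, `relative` and (when
#'   available) `relerr`.
#' @export
extract_profile <- function(grid, axis = c("x", "y", "z"),
                            point = c(0, 0, 0)) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  d <- dim(grid$dose)
  idx <- round((point - grid$origin) / grid$voxel) + 1
  if (any(idx < 1 | idx > d)) stop("point outside the dose grid")
  sel <- as.list(idx)
  sel[[ai]] <- seq_len(d[ai])
  dose <- grid$dose[sel[[1]], sel[[2]], sel[[3]]]
  err <- grid$relerr[sel[[1]], sel[[2]], sel[[3]]]
  anchor <- grid$dose[idx[1], idx[2], idx[3]]
  if (anchor <= 0) stop("zero dose at the normalisation point")
  data.frame(position_mm = grid$origin[ai] + (seq_len(d[ai]) - 1) * grid$voxel,
             dose = dose, relative = dose / anchor, relerr = err)
}

#' Full width at half maximum of a profile
#'
#' Linear interpolation of the half-maximum crossings on both sides of the
#' profile peak.
#'
#' @param profile data.frame from [extract_profile()] (uses `relative`).
#' @return FWHM in mm (NA when a crossing is missing).
#' @export
profile_fwhm <- function(profile) {
  x <- profile$position_mm
  y <- profile$relative / max(profile$relative)
  ip <- which.max(y)
  half <- 0.5
  cross <- function(side) {
    idx <- if (side == "left") seq_len(ip) else seq(ip, length(y))
    yy <- y[idx]; xx <- x[idx]
    below <- which(yy < half)
    if (!length(below)) return(NA_real_)
    if (side == "left") {
      i <- max(below)
      if (i == length(yy)) return(NA_real_)
      xx[i] + (half - yy[i]) / (yy[i + 1] - yy[i]) * (xx[i + 1] - xx[i])
    } else {
      i <- min(below)
      if (i == 1) return(NA_real_)
      xx[i - 1] + (half - yy[i - 1]) / (yy[i] - yy[i - 1]) * (xx[i] - xx[i - 1])
    }
  }
  cross("right") - cross("left")
}

#' Cumulative dose-volume histogram
#'
#' @param grid A `gk_dose_grid` (or a numeric dose array).
#' @param mask Logical array selecting the structure voxels (nonempty).
#' @param bin_width Dose bin width in the grid's dose units (default 0.05).
#' @return A `gk_dvh` data.frame with `dose` (left bin edges, starting at 0)
#'   and `volume` (fraction of the structure receiving at least that dose);
#'   `volume[1]` is 1 and the curve is nonincreasing.
#' @export
compute_dvh <- function(grid, mask, bin_width = 0.05) {
  dose <- if (inherits(grid, "gk_dose_grid")) grid$dose else grid
  if (is.null(mask)) stop("empty mask")
  v <- dose[mask]
  if (!length(v)) stop("empty mask")
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  vol <- vapply(edges, function(e) mean(v >= e), numeric(1))
  structure(data.frame(dose = edges, volume = vol),
            class = c("gk_dvh", "data.frame"), n_voxels = length(v))
}

#' Dxx metrics from a DVH
#'
#' The minimum dose received by xx% of the structure volume, interpolated
#' linearly between DVH bins.
#'
#' @param dvh A `gk_dvh`.
#' @param xx Percent volume levels (e.g. `c(50, 70, 90, 95)`).
#' @return Named numeric vector of doses.
#' @export
dvh_dxx <- function(dvh, xx = c(50, 70, 90, 95)) {
  frac <- xx / 100
  out <- vapply(frac, function(f) {
    if (f > dvh$volume[1]) return(0)
    # volume is nonincreasing in dose: find the crossing
    i <- max(which(dvh$volume >= f))
    if (i == nrow(dvh)) return(dvh$dose[i])
    v1 <- dvh$volume[i]; v2 <- dvh$volume[i + 1]
    if (v2 == v1) return(dvh$dose[i])
    dvh$dose[i] + (v1 - f) / (v1 - v2) * (dvh$dose[i + 1] - dvh$dose[i])
  }, numeric(1))
  names(out) <- paste0("D", xx)
  out
}

#' Fraction of a structure covered by a dose level
#'
#' @param grid A `gk_dose_grid` or dose array.
#' @param mask Logical structure mask.
#' @param level Dose level in grid units.
#' @return Fraction of structure voxels with dose >= level.
#' @export
coverage <- function(grid, mask, level) {
  dose <- if (inherits(grid, "gk_dose_grid")) grid$dose else grid
  v <- dose[mask]
  if (!length(v)) stop("empty mask")
  mean(v >= level)
}

#' Write a DVH as CSV (dose, cumulative volume fraction)
#' @param dvh A `gk_dvh`.
#' @param path Output file.
#' @export
write_dvh <- function(dvh, path) {
  utils::write.csv(as.data.frame(dvh), path, row.names = FALSE)
  invisible(path)
}
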