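#' Default ring geometry of the virtual source array
#'
#' One row per latitudinal ring: polar angle of the source-to-focus ray
#' measured from the cylinder (+z) axis, nominal source-to-focus distance,
#' and the number of sources the ring contributes to each sector. The angles
#' place the five film rows of one sector between z = 54 mm and z = 130 mm on
#' the 113 mm radius measurement cylinder so that all 24 spots stay separated
#' for the 16 mm collimator; the distances sit in the nominal 380-420 mm
#' regime and are refined later by [tune_parameters()]. The ring
#' multiplicities are the vector derived by [derive_ring_multiplicities()].
#'
#' These defaults are documented stand-ins for the manufacturer's proprietary
#' arrangement: they only need to be in the right regime, because the
#' calibration step adjusts the effective distances per collimator.
#'
#' @param cylinder_radius Film cylinder radius in mm (226 mm diameter phantom).
#' @return A data.frame with columns `ring`, `phi_deg`, `R_s_mm`,
#'   `multiplicity` and attribute `cylinder_radius`.
#' @export
pfx_ring_geometry <- function(cylinder_radius = 113) {
  z_row <- c(54, 73, 92, 111, 130)
  geom <- data.frame(
    ring = 1:5,
    phi_deg = atan2(cylinder_radius, z_row) * 180 / pi,
    R_s_mm = rep(400, 5),
    multiplicity = c(5, 5, 5, 5, 4)
  )
  attr(geom, "cylinder_radius") <- cylinder_radius
  geom
}

#' Azimuth offsets of one ring's sources within a sector
#'
#' Sources of a ring are evenly spread over the 45 degree sector span and
#' centred on the sector axis.
#'
#' @param n Number of sources the ring contributes to a sector.
#' @return Numeric vector of azimuth offsets in degrees relative to the
#'   sector axis.
#' @export
ring_azimuth_offsets <- function(n) {
  stopifnot(n >= 1)
  (seq_len(n) - (n + 1) / 2) * (45 / n)
}

#' Build the 192-source virtual point-source array
#'
#' Expands a per-ring geometry table into one descriptor per source: 8
#' sectors times 24 sources, five rings per sector. Sector k is sector 1
#' rotated by (k-1) x 45 degrees about the cylinder axis. The focus of the
#' untranslated array is the origin; a source sits at distance `R_s` from the
#' focus along the unit vector with polar angle `phi` and its azimuth.
#'
#' @param geometry Ring geometry table as from [pfx_ring_geometry()].
#' @return A data.frame of class `gk_source_array` with one row per source:
#'   `ring`, `sector`, `index` (1-24 within the sector), `azimuth_deg`,
#'   `phi_deg`, `R_s_mm`.
#' @export
build_source_array <- function(geometry = pfx_ring_geometry()) {
  req <- c("ring", "phi_deg", "R_s_mm", "multiplicity")
  if (!all(req %in% names(geometry)))
    stop("geometry table must have columns ", paste(req, collapse = ", "))
  if (nrow(geometry) != 5) stop("geometry table must have 5 rings")
  if (sum(geometry$multiplicity) != 24)
    stop("configuration error: ring multiplicities sum to ",
         sum(geometry$multiplicity), ", expected 24 per sector")
  if (any(geometry$R_s_mm <= 0))
    stop("configuration error: nonpositive source-to-focus distance")
  if (any(geometry$phi_deg <= 0 | geometry$phi_deg >= 180))
    stop("configuration error: phi must lie in (0, 180) degrees")

  per_sector <- do.call(rbind, lapply(seq_len(nrow(geometry)), function(i) {
    off <- ring_azimuth_offsets(geometry$multiplicity[i])
    data.frame(ring = geometry$ring[i], offset_deg = off,
               phi_deg = geometry$phi_deg[i], R_s_mm = geometry$R_s_mm[i])
  }))
  per_sector <- per_sector[order(per_sector$ring, per_sector$offset_deg), ]
  per_sector$index <- seq_len(nrow(per_sector))

  arr <- do.call(rbind, lapply(1:8, function(k) {
    s <- per_sector
    s$sector <- k
    s$azimuth_deg <- (s$offset_deg + (k - 1) * 45) %% 360
    s
  }))
  arr <- arr[, c("ring", "sector", "index", "azimuth_deg", "phi_deg", "R_s_mm")]
  rownames(arr) <- NULL
  attr(arr, "cylinder_radius") <- attr(geometry, "cylinder_radius") %||% 113
  class(arr) <- c("gk_source_array", "data.frame")
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cartesian positions of sources (untranslated array, focus at origin)
#'
#' @param array A `gk_source_array`.
#' @return Matrix with columns x, y, z in mm.
#' @export
source_positions <- function(array) {
  az <- array$azimuth_deg * pi / 180
  ph <- array$phi_deg * pi / 180
  cbind(x = array$R_s_mm * sin(ph) * cos(az),
        y = array$R_s_mm * sin(ph) * sin(az),
        z = array$R_s_mm * cos(ph))
}

#' @export
print.gk_source_array <- function(x, ...) {
  cat(sprintf("<gk_source_array> %d sources, %d sectors, rings %s\n",
              nrow(x), length(unique(x$sector)),
              paste(sort(unique(x$ring)), collapse = ",")))
  cat(sprintf("  per-sector ring multiplicity: %s\n",
              paste(table(x$ring[x$sector == 1]), collapse = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# shots and plans
# ---------------------------------------------------------------------------

#' Create a shot (one irradiation configuration)
#'
#' @param focus Numeric length-3 focus position in mm (frame coordinates).
#' @param states Character vector of 8 per-sector collimator states, each one
#'   of `"4"`, `"8"`, `"16"`, `"blocked"`.
#' @param time Beam-on time in minutes.
#' @return A `gk_shot` list.
#' @export
gk_shot <- function(focus, states, time) {
  if (length(focus) != 3 || !is.numeric(focus)) stop("focus must be xyz in mm")
  states <- as.character(states)
  if (length(states) != 8) stop("a shot needs 8 sector states")
  if (!all(states %in% c("4", "8", "16", "blocked")))
    stop("sector states must be one of 4, 8, 16, blocked")
  if (!is.numeric(time) || time < 0) stop("shot time must be >= 0 minutes")
  structure(list(focus = as.numeric(focus), states = states,
                 time = as.numeric(time)), class = "gk_shot")
}

#' Create a treatment plan
#'
#' @param shots List of [gk_shot()] objects (at least one).
#' @param dose_rate Dose rate in Gy/min (> 0).
#' @param prescription_dose Prescription dose in Gy.
#' @param prescription_isodose Prescription isodose as a fraction (e.g. 0.5).
#' @return A `gk_plan` list.
#' @export
gk_plan <- function(shots, dose_rate, prescription_dose = NA_real_,
                    prescription_isodose = 0.5) {
  if (inherits(shots, "gk_shot")) shots <- list(shots)
  if (length(shots) < 1) stop("a plan needs at least one shot")
  if (!all(vapply(shots, inherits, logical(1), "gk_shot")))
    stop("shots must be gk_shot objects")
  if (!is.numeric(dose_rate) || dose_rate <= 0) stop("dose rate must be > 0")
  structure(list(shots = shots, dose_rate = dose_rate,
                 prescription_dose = prescription_dose,
                 prescription_isodose = prescription_isodose),
            class = "gk_plan")
}

#' @export
print.gk_plan <- function(x, ...) {
  cat(sprintf("<gk_plan> %d shot(s), dose rate %.3g Gy/min\n",
              length(x$shots), x$dose_rate))
  if (is.finite(x$prescription_dose))
    cat(sprintf("  prescription %.3g Gy to %.0f%% isodose\n",
                x$prescription_dose, 100 * x$prescription_isodose))
  invisible(x)
}

#' Read / write a plan as JSON
#'
#' The plan file lists shots (focus mm, 8 sector states, time min), the dose
#' rate and the prescription.
#'
#' @param path File path.
#' @return [read_plan()] returns a `gk_plan`.
#' @export
read_plan <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shots <- lapply(j$shots, function(s)
    gk_shot(unlist(s$focus), unlist(s$states), s$time))
  gk_plan(shots, dose_rate = j$dose_rate,
          prescription_dose = j$prescription_dose %||% NA_real_,
          prescription_isodose = j$prescription_isodose %||% 0.5)
}

#' @param plan A `gk_plan`.
#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  j <- list(shots = lapply(plan$shots, function(s)
    list(focus = s$focus, states = s$states, time = s$time)),
    dose_rate = plan$dose_rate,
    prescription_dose = plan$prescription_dose,
    prescription_isodose = plan$prescription_isodose)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Translate the source array to a shot's focus
#'
#' The phantom stays still; the whole source arrangement is rigidly
#' translated so that the beam focus coincides with the shot's focus
#' position. Sources of blocked sectors are dropped.
#'
#' @param shot A [gk_shot()].
#' @param array A `gk_source_array`.
#' @param phantom Optional `gk_phantom`; a warning is issued when the focus
#'   lies outside its bounding volume.
#' @return A data.frame like `array` restricted to open sectors, with added
#'   columns `x`, `y`, `z` (translated source positions, mm), `collimator`
#'   (per-sector state) and attribute `focus`.
#' @export
shot_transform <- function(shot, array, phantom = NULL) {
  stopifnot(inherits(shot, "gk_shot"))
  if (!is.null(phantom)) {
    bb <- phantom_bbox(phantom)
    f <- shot$focus
    if (any(f < bb$lo | f > bb$hi))
      warning("shot focus lies outside the phantom bounding volume")
  }
  open <- which(shot$states != "blocked")
  out <- array[array$sector %in% open, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("all 8 sectors blocked: empty transformed array")
  }
  pos <- if (nrow(out)) source_positions(out) else
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  out$x <- pos[, 1] + shot$focus[1]
  out$y <- pos[, 2] + shot$focus[2]
  out$z <- pos[, 3] + shot$focus[3]
  out$collimator <- shot$states[out$sector]
  attr(out, "focus") <- shot$focus
  attr(out, "cylinder_radius") <- attr(array, "cylinder_radius")
  rownames(out) <- NULL
  out
}
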