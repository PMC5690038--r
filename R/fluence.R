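# Per-source fluence maps: extraction from films, masking, cylinder mapping,
# shot-level combination and source-particle sampling.

#' Map film-plane coordinates onto the measurement cylinder
#'
#' The film is wrapped on a cylinder of radius `R` about the z axis; the arc
#' coordinate `x_s` unrolls the azimuth and `y_s` is axial:
#' \eqn{x = R\cos(x_s/R),\; y = R\sin(x_s/R),\; z = y_s}.
#'
#' @param x_s,y_s Film coordinates in mm (vectorised).
#' @param R Cylinder radius in mm.
#' @param sector_ref_deg Azimuth of the film's x_s = 0 line in degrees.
#' @return Matrix with columns x, y, z (mm); all points satisfy
#'   x^2 + y^2 = R^2.
#' @export
film_to_cylinder <- function(x_s, y_s, R = 113, sector_ref_deg = 0) {
  if (any(abs(x_s) > pi * R + 1e-9))
    stop("wrap error: |x_s| exceeds pi * R, film would overlap itself")
  ang <- x_s / R + sector_ref_deg * pi / 180
  cbind(x = R * cos(ang), y = R * sin(ang), z = y_s)
}

#' Extract per-source fluence maps from a processed film
#'
#' Thresholds the image at a fixed fraction of its maximum, labels connected
#' components, and returns one fluence map per component with its
#' intensity-weighted (dosimetric) centroid. The number of components must
#' equal the expected source count.
#'
#' @param film A `gk_film`, normally after [smooth_and_open()].
#' @param expected Expected number of sources (24 for one sector).
#' @param background Segmentation level as a fraction of the image maximum.
#' @param array Optional source array used to tag each map with its
#'   (ring, sector, index) by nearest predicted projection point.
#' @return List of `gk_fluence_map` objects, ordered by (ring, index) when
#'   tagged. Each map holds `values` (matrix normalised to peak 1, zero
#'   outside the component), `x`, `y` coordinate vectors, `pitch`,
#'   `bixel_area` (pitch^2, mm^2), `centroid` (mm), `strength` (the raw peak
#'   intensity, carrying the collimator/ring exposure level),
#'   `cylinder_radius`, `sector_ref_deg`, `collimator` and `tag`.
#' @export
extract_sources <- function(film, expected = 24, background = 0.02,
                            array = NULL) {
  stopifnot(inherits(film, "gk_film"))
  img <- film$intensity
  mask <- img > background * max(img)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n != expected)
    stop(sprintf("segmentation error: found %d source components, expected %d",
                 n, expected))
  ref_az <- (film$sector - 1) * 45
  maps <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- lab == k
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    vals <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    vals[!sel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]] <- 0
    xk <- film$x[cols[1]:cols[2]]
    yk <- film$y[rows[1]:rows[2]]
    w <- sum(vals)
    cx <- sum(vals %*% cbind(xk)) / w
    cy <- sum(yk * rowSums(vals)) / w
    peak <- max(vals)
    maps[[k]] <- structure(list(
      values = vals / peak, x = xk, y = yk, pitch = film$pitch_mm,
      bixel_area = film$pitch_mm^2, centroid = c(x_s = cx, y_s = cy),
      strength = peak, cylinder_radius = film$cylinder_radius,
      sector_ref_deg = ref_az, collimator = film$collimator,
      mask_threshold = NA_real_,
      tag = list(ring = NA_integer_, sector = film$sector,
                 index = NA_integer_)), class = "gk_fluence_map")
  }
  if (!is.null(array)) {
    src <- array[array$sector == film$sector, , drop = FALSE]
    R <- film$cylinder_radius
    px <- R * ((((src$azimuth_deg - ref_az + 180) %% 360) - 180) * pi / 180)
    py <- R / tan(src$phi_deg * pi / 180)
    cen <- t(vapply(maps, `[[`, numeric(2), "centroid"))
    used <- integer(0)
    for (k in seq_len(n)) {
      d2 <- (px - cen[k, 1])^2 + (py - cen[k, 2])^2
      j <- which.min(d2)
      if (j %in% used)
        stop("segmentation error: two components map to the same source")
      used <- c(used, j)
      maps[[k]]$tag <- list(ring = src$ring[j], sector = film$sector,
                            index = src$index[j])
    }
    ord <- order(vapply(maps, function(m) m$tag$index, integer(1)))
    maps <- maps[ord]
  }
  maps
}

#' @export
print.gk_fluence_map <- function(x, ...) {
  cat(sprintf(
    "<gk_fluence_map> %dx%d bixels, pitch %.3f mm, centroid (%.2f, %.2f) mm",
    nrow(x$values), ncol(x$values), x$pitch, x$centroid[1], x$centroid[2]))
  if (!is.na(x$tag$ring))
    cat(sprintf(", ring %d sector %d index %d", x$tag$ring, x$tag$sector,
                x$tag$index))
  cat("\n")
  invisible(x)
}

#' Source angles from a fluence-map centroid
#'
#' Inverts the cylinder projection: the azimuth follows from the arc
#' coordinate, `x_s / R`, added to the sector reference azimuth, and the
#' latitudinal (polar) angle from the axial coordinate,
#' \eqn{\phi = \mathrm{atan2}(R, y_s)}.
#'
#' @param map A `gk_fluence_map` (or a length-2 centroid vector).
#' @param R Cylinder radius mm (taken from the map when available).
#' @param sector_ref_deg Sector reference azimuth in degrees.
#' @return data.frame with `azimuth_deg`, `phi_deg` and `z_mm` (the axial
#'   spot position).
#' @export
centroid_to_angles <- function(map, R = NULL, sector_ref_deg = NULL) {
  if (inherits(map, "gk_fluence_map")) {
    cen <- map$centroid
    R <- R %||% map$cylinder_radius
    sector_ref_deg <- sector_ref_deg %||% map$sector_ref_deg
  } else {
    cen <- map
    R <- R %||% 113
    sector_ref_deg <- sector_ref_deg %||% 0
  }
  data.frame(azimuth_deg = sector_ref_deg + cen[[1]] / R * 180 / pi,
             phi_deg = atan2(R, cen[[2]]) * 180 / pi,
             z_mm = cen[[2]])
}

#' Apply the fluence mask filter
#'
#' Pixels whose relative intensity exceeds the threshold are set to 1; the
#' surrounding penumbra pixels keep their relative intensity in (0, 1). The
#' threshold is the fine-tuning knob of the output-factor calibration.
#'
#' @param map A `gk_fluence_map`.
#' @param threshold Fraction in [0, 1).
#' @return The masked `gk_fluence_map`.
#' @export
apply_mask_threshold <- function(map, threshold) {
  stopifnot(inherits(map, "gk_fluence_map"))
  if (threshold < 0 || threshold >= 1)
    stop("mask threshold must lie in [0, 1)")
  if (threshold >= max(map$values))
    stop("empty core error: threshold >= maximum map intensity")
  map$values[map$values > threshold] <- 1
  map$mask_threshold <- threshold
  map
}

#' Integrated fluence mass of a map (intensity times bixel area)
#' @param map A `gk_fluence_map`.
#' @return Scalar, mm^2 units.
#' @export
fluence_mass <- function(map) sum(map$values) * map$bixel_area

#' Support area of a map (area of its nonzero bixels)
#' @param map A `gk_fluence_map`.
#' @return Scalar, mm^2.
#' @export
fluence_support_area <- function(map) sum(map$values > 0) * map$bixel_area

# ---------------------------------------------------------------------------
# shot-level fluence configuration
# ---------------------------------------------------------------------------

#' Combine per-source fluence maps into a sampling configuration for a plan
#'
#' A shot opens up to 8 sectors; sector k reuses the sector-1 maps rotated by
#' (k-1) x 45 degrees. Every map instance is tagged with its source: the
#' virtual point source sits at distance `R_s(collimator, ring)` from the
#' focus along the ray through the map centroid, translated to the shot's
#' focus. The whole configuration is sampled at once (bixel probability
#' proportional to masked intensity x bixel area x source strength x shot
#' time), which makes the simulation cost independent of the shot count.
#'
#' @param plan A [gk_plan()] or single [gk_shot()].
#' @param maps Named list `list("4"=, "8"=, "16"=)` of 24 sector-1 maps per
#'   collimator (tagged, usually masked). Collimators not used by the plan
#'   may be omitted.
#' @param R_s Either a named list/matrix of per-collimator, per-ring
#'   source-to-focus distances (rows "4","8","16", 5 columns) or `NULL` to
#'   take distances from `geometry`.
#' @param geometry Ring geometry table (fallback distances).
#' @return A `gk_fluence_config`: list of unique `maps` (raw arrays for the
#'   transport kernel), an `instances` data.frame and `total_weight`
#'   (sum of instance weights; the mass-time normalisation of dose scores).
#' @export
build_shot_fluence <- function(plan, maps, R_s = NULL,
                               geometry = pfx_ring_geometry()) {
  if (inherits(plan, "gk_shot")) plan <- gk_plan(list(plan), dose_rate = 1)
  stopifnot(inherits(plan, "gk_plan"))
  rs_lookup <- function(coll, ring) {
    if (is.null(R_s)) return(geometry$R_s_mm[ring])
    if (is.matrix(R_s)) return(R_s[as.character(coll), ring])
    R_s[[as.character(coll)]][ring]
  }
  uniq <- list()   # raw map arrays for the kernel, keyed by collimator/index
  inst <- list()
  key_id <- character(0)
  for (si in seq_along(plan$shots)) {
    shot <- plan$shots[[si]]
    if (shot$time <= 0 && length(plan$shots) > 1) next
    for (sec in which(shot$states != "blocked")) {
      coll <- shot$states[sec]
      mm <- maps[[coll]]
      if (is.null(mm))
        stop("no fluence maps supplied for collimator ", coll)
      for (m in mm) {
        key <- paste0(coll, "#", m$tag$index)
        mid <- match(key, key_id)
        if (is.na(mid)) {
          key_id <- c(key_id, key)
          uniq[[length(uniq) + 1]] <- list(
            values = m$values, x0 = m$x[1], y0 = m$y[1], pitch = m$pitch,
            R = m$cylinder_radius)
          mid <- length(uniq)
        }
        ang <- centroid_to_angles(m)
        rsv <- rs_lookup(coll, m$tag$ring)
        az <- (ang$azimuth_deg + (sec - 1) * 45) * pi / 180
        phr <- ang$phi_deg * pi / 180
        spos <- rsv * c(sin(phr) * cos(az), sin(phr) * sin(az), cos(phr)) +
          shot$focus
        w <- shot$time * m$strength * fluence_mass(m)
        inst[[length(inst) + 1]] <- data.frame(
          map_id = mid, sx = spos[1], sy = spos[2], sz = spos[3],
          rot_deg = (sec - 1) * 45, weight = w,
          tx = shot$focus[1], ty = shot$focus[2], tz = shot$focus[3],
          shot = si, sector = sec, ring = m$tag$ring, index = m$tag$index,
          collimator = coll, R_s = rsv, time = shot$time)
      }
    }
  }
  if (!length(inst))
    stop("zero-mass fluence: no open sector with positive time in the plan")
  inst <- do.call(rbind, inst)
  if (all(inst$weight <= 0)) stop("zero-mass fluence: all weights are zero")
  structure(list(maps = uniq, instances = inst,
                 total_weight = sum(inst$weight),
                 dose_rate = plan$dose_rate),
            class = "gk_fluence_config")
}

#' @export
print.gk_fluence_config <- function(x, ...) {
  cat(sprintf(
    "<gk_fluence_config> %d source instances over %d unique maps, total weight %.4g\n",
    nrow(x$instances), length(x$maps), x$total_weight))
  invisible(x)
}

#' Sample source particles from a fluence configuration
#'
#' Reference R implementation of the sampler used inside the transport
#' kernel: pick a source instance with probability proportional to its
#' weight, then a bixel proportional to intensity, jitter uniformly within
#' the bixel, map to the cylinder, and direct the particle from the tagged
#' source point through the sampled position. The particle's statistical
#' weight is the planned shot time.
#'
#' @param config A `gk_fluence_config`.
#' @param n Number of particles.
#' @param seed Seed.
#' @return data.frame with position (x,y,z), direction (ux,uy,uz), `weight`,
#'   `instance`, `bixel`.
#' @export
sample_particle <- function(config, n, seed = 1) {
  stopifnot(inherits(config, "gk_fluence_config"), n >= 1)
  if (config$total_weight <= 0) stop("zero-mass fluence")
  set.seed(seed)
  ins <- config$instances
  ii <- sample.int(nrow(ins), n, replace = TRUE, prob = ins$weight)
  out <- matrix(NA_real_, n, 7)
  bix <- integer(n)
  for (mid in unique(ins$map_id[ii])) {
    rows <- which(ins$map_id[ii] == mid)
    m <- config$maps[[mid]]
    v <- m$values
    pos <- which(v > 0)
    b <- pos[sample.int(length(pos), length(rows), replace = TRUE,
                        prob = v[pos])]
    bix[rows] <- b
    iy <- (b - 1) %% nrow(v) + 1
    ix <- (b - 1) %/% nrow(v) + 1
    xs <- m$x0 + (ix - 1) * m$pitch + (runif(length(rows)) - 0.5) * m$pitch
    ys <- m$y0 + (iy - 1) * m$pitch + (runif(length(rows)) - 0.5) * m$pitch
    for (j in seq_along(rows)) {
      k <- ii[rows[j]]
      p0 <- film_to_cylinder(xs[j], ys[j], m$R,
                             sector_ref_deg = ins$rot_deg[k])
      p <- p0 + c(ins$tx[k], ins$ty[k], ins$tz[k])
      s <- c(ins$sx[k], ins$sy[k], ins$sz[k])
      u <- p - s
      u <- u / sqrt(sum(u^2))
      out[rows[j], ] <- c(p, u, ins$time[k])
    }
  }
  res <- as.data.frame(out)
  names(res) <- c("x", "y", "z", "ux", "uy", "uz", "weight")
  res$instance <- ii
  res$bixel <- bix
  res
}
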