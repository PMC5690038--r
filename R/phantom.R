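# Voxel phantoms: analytic sphere/cylinder generators and slice-wise fill of
# planar contour structures with water.

#' Build a water voxel phantom
#'
#' Generates a water-filled (1.0 g/cm^3) voxel geometry surrounded by vacuum.
#' Spheres and cylinders are generated analytically; structure sets are
#' filled slice by slice with an even-odd point-in-polygon test at voxel
#' centres, matching the planning system's water-equivalent assumption.
#'
#' @param kind `"sphere"`, `"cylinder"` or `"from_structure"`.
#' @param radius Sphere/cylinder radius in mm.
#' @param height Cylinder height in mm.
#' @param center Centre of the phantom in mm (frame coordinates).
#' @param voxel Isotropic voxel size in mm (default 1).
#' @param margin Vacuum margin around the object in mm.
#' @param structures A structure set (see [read_structures()]); its first
#'   structure defines the fill surface unless `structure_name` is given.
#' @param structure_name Name of the structure to fill.
#' @return A `gk_phantom`: list with `density` (3D array, g/cm^3), `voxel`
#'   (mm), `origin` (mm position of the centre of voxel [1,1,1]).
#' @export
make_phantom <- function(kind = c("sphere", "cylinder", "from_structure"),
                         radius = 80, height = 160, center = c(0, 0, 0),
                         voxel = 1, margin = 0, structures = NULL,
                         structure_name = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("sphere", "cylinder")) {
    stopifnot(radius > 0, voxel > 0)
    half <- c(radius, radius, if (kind == "sphere") radius else height / 2) +
      margin
    # odd voxel counts: a voxel centre coincides with the phantom centre,
    # so the focus voxel of a centred shot is the grid centre
    n <- 2L * as.integer(ceiling(half / voxel - 0.5)) + 1L
    origin <- center - (n - 1) / 2 * voxel
    ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * voxel)
    dx2 <- (ax[[1]] - center[1])^2
    dy2 <- (ax[[2]] - center[2])^2
    dz <- ax[[3]] - center[3]
    dens <- array(0, dim = n)
    if (kind == "sphere") {
      for (k in seq_len(n[3])) {
        r2 <- radius^2 - dz[k]^2
        if (r2 > 0) dens[, , k] <- (outer(dx2, dy2, `+`) <= r2) * 1.0
      }
    } else {
      disk <- (outer(dx2, dy2, `+`) <= radius^2) * 1.0
      # half-open in z so boundary-tied voxel centres count once
      for (k in seq_len(n[3]))
        if (dz[k] >= -height / 2 && dz[k] < height / 2) dens[, , k] <- disk
    }
  } else {
    stopifnot(!is.null(structures))
    sname <- structure_name %||% names(structures)[1]
    contours <- structures[[sname]]
    if (is.null(contours) || length(contours) == 0) {
      warning("empty structure set: all-vacuum phantom")
      n <- pmax(1L, as.integer(ceiling(2 * (c(10, 10, 10) + margin) / voxel)))
      origin <- center - (n - 1) / 2 * voxel
      dens <- array(0, dim = n)
    } else {
      allv <- do.call(rbind, lapply(contours, function(ct) {
        if (nrow(ct$vertices) < 3) stop("degenerate contour: < 3 vertices")
        cbind(ct$vertices, ct$z)
      }))
      lo <- apply(allv, 2, min) - margin
      hi <- apply(allv, 2, max) + margin
      n <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
      origin <- lo
      ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * voxel)
      dens <- array(0, dim = n)
      zs <- vapply(contours, `[[`, numeric(1), "z")
      for (k in seq_len(n[3])) {
        near <- which(abs(zs - ax[[3]][k]) <= voxel / 2)
        if (!length(near)) next
        inside <- matrix(FALSE, n[1], n[2])
        for (ci in near) {
          v <- contours[[ci]]$vertices
          gx <- rep(ax[[1]], times = n[2])
          gy <- rep(ax[[2]], each = n[1])
          hit <- point_in_polygon(gx, gy, v[, 1], v[, 2])
          inside <- xor(inside, matrix(hit, n[1], n[2]))  # even-odd stack
        }
        dens[, , k] <- inside * 1.0
      }
    }
    origin <- as.numeric(origin)
  }
  structure(list(density = dens, voxel = voxel, origin = as.numeric(origin)),
            class = "gk_phantom")
}

#' Even-odd (crossing number) point-in-polygon test
#'
#' @param px,py Query points (vectorised).
#' @param vx,vy Polygon vertices (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @export
print.gk_phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf(
    "<gk_phantom> %d x %d x %d voxels at %.3g mm, water volume %.4g cm^3\n",
    d[1], d[2], d[3], x$voxel, phantom_volume(x)))
  invisible(x)
}

#' Water volume of a phantom in cm^3
#' @param phantom A `gk_phantom`.
#' @export
phantom_volume <- function(phantom)
  sum(phantom$density > 0) * phantom$voxel^3 / 1000

#' Bounding box of a phantom
#' @param phantom A `gk_phantom`.
#' @return list(lo, hi) in mm.
#' @export
phantom_bbox <- function(phantom) {
  d <- dim(phantom$density)
  list(lo = phantom$origin - phantom$voxel / 2,
       hi = phantom$origin + (d - 0.5) * phantom$voxel)
}

#' Read / write a structure set (per-slice contour polygons) as JSON
#'
#' Format: named structures, each a list of contours with a slice `z` (mm)
#' and an n x 2 `vertices` matrix (mm). Polygons are closed implicitly and
#' must be non-self-intersecting with at least 3 vertices.
#'
#' @param path JSON file path.
#' @return Named list of structures; each structure is a list of
#'   `list(z=, vertices=)` contours.
#' @export
read_structures <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(j, function(s) lapply(s, function(ct) {
    v <- do.call(rbind, lapply(ct$vertices, unlist))
    if (nrow(v) < 3) stop("degenerate contour: < 3 vertices")
    list(z = ct$z, vertices = v)
  }))
  out
}

#' @param structures Structure set.
#' @rdname read_structures
#' @export
write_structures <- function(structures, path) {
  j <- lapply(structures, function(s) lapply(s, function(ct)
    list(z = ct$z, vertices = apply(ct$vertices, 1, as.list))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Voxelise a structure onto a phantom/dose grid
#'
#' @param phantom A `gk_phantom` (or `gk_dose_grid`) providing the grid.
#' @param contours One structure: list of `list(z=, vertices=)`.
#' @return Logical 3D mask.
#' @export
structure_mask <- function(phantom, contours) {
  d <- dim(phantom$density %||% phantom$dose)
  ax <- lapply(1:3, function(a)
    phantom$origin[a] + (seq_len(d[a]) - 1) * phantom$voxel)
  mask <- array(FALSE, dim = d)
  zs <- vapply(contours, `[[`, numeric(1), "z")
  for (k in seq_len(d[3])) {
    near <- which(abs(zs - ax[[3]][k]) <= phantom$voxel / 2)
    if (!length(near)) next
    inside <- matrix(FALSE, d[1], d[2])
    for (ci in near) {
      v <- contours[[ci]]$vertices
      gx <- rep(ax[[1]], times = d[2])
      gy <- rep(ax[[2]], each = d[1])
      inside <- xor(inside, matrix(point_in_polygon(gx, gy, v[, 1], v[, 2]),
                                   d[1], d[2]))
    }
    mask[, , k] <- inside
  }
  mask
}
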