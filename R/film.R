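# Synthetic panoramic films and the film image-processing steps
# (anisotropic diffusion smoothing + grayscale morphological opening).

#' Film scan resolutions per collimator
#'
#' Default scan settings: 240, 150 and 96 dpi for the 4, 8 and 16 mm
#' collimators.
#' @param collimator `"4"`, `"8"` or `"16"`.
#' @return dpi (scalar).
#' @export
film_dpi <- function(collimator) {
  switch(as.character(collimator), "4" = 240, "8" = 150, "16" = 96,
         stop("collimator must be 4, 8 or 16"))
}

#' Spot model for synthetic films
#'
#' Each source image is a flat core with an error-function (sigmoid) penumbra.
#' The core radius on the film follows from projecting the collimator field
#' size at the focus back to the cylinder surface; `penumbra_sigma` is the
#' sigmoid width on the film in mm; `peak` is the collimator's relative
#' exposure level — the film records less dose through the smaller
#' apertures. The defaults (0.88, 0.95, 1.0) represent relative *primary*
#' transmission: they sit above the total collimator output factors because
#' the focal dose of a small field additionally loses phantom-scatter
#' contribution, an effect the transport model produces by itself. `noise`
#' is the additive Gaussian noise level relative to the peak.
#'
#' @param collimator `"4"`, `"8"` or `"16"`.
#' @param penumbra_sigma Penumbra sigmoid width, mm on the film.
#' @param peak Relative peak exposure of this collimator's spots.
#' @param noise Relative additive noise level.
#' @return List with elements `collimator`, `penumbra_sigma`, `peak`, `noise`.
#' @export
spot_model <- function(collimator,
                       penumbra_sigma = c("4" = 0.35, "8" = 0.5, "16" = 0.6)[[as.character(collimator)]],
                       peak = c("4" = 0.88, "8" = 0.95, "16" = 1.0)[[as.character(collimator)]],
                       noise = 0.01) {
  stopifnot(penumbra_sigma > 0, peak > 0, noise >= 0)
  list(collimator = as.character(collimator), penumbra_sigma = penumbra_sigma,
       peak = peak, noise = noise)
}

#' Relative per-ring brightness of the emulated machine
#'
#' The panoramic film of a real unit shows ring-to-ring exposure differences
#' that carry the machine's relative ring outputs. The synthetic generator
#' reproduces them by scaling each ring's spot amplitude so that the
#' emulated machine's per-ring outputs follow that collimator's manufacturer
#' reference column shipped with the package (the ring pattern genuinely
#' differs between collimators: aperture occlusion depends on both ring and
#' collimator). Two geometric factors link film exposure to output at the
#' focus: the beam-spread factor \eqn{(1 - a_r/R_r)^2} (with
#' \eqn{a_r = L/\sin\phi_r} the focus-to-cylinder distance along the ray)
#' between film and focus, and the obliquity projection \eqn{\sin\phi_r} of
#' the beam flux onto the film surface. Hence
#' \eqn{\rho_r \propto f^{c}_r \sin\phi_r / (1 - a_r/R_r)^2}, normalised to
#' ring 2.
#'
#' @param geometry Ring geometry table.
#' @param collimator Which collimator's reference ring outputs to emulate.
#' @param f_reference Optional explicit per-ring output factors (ring 1-5),
#'   overriding the shipped reference column.
#' @return Numeric vector of 5 relative brightness factors (ring 2 = 1).
#' @export
ring_brightness <- function(geometry = pfx_ring_geometry(),
                            collimator = "16", f_reference = NULL) {
  if (is.null(f_reference)) {
    ref <- reference_output_factors()
    sub <- ref$rings[ref$rings$collimator == as.character(collimator), ]
    f_reference <- sub$manufacturer[order(sub$ring)]
  }
  L <- attr(geometry, "cylinder_radius") %||% 113
  sinphi <- sin(geometry$phi_deg * pi / 180)
  a <- L / sinphi
  g <- (1 - a / geometry$R_s_mm)^2
  rho <- f_reference / (g / g[2]) * (sinphi / sinphi[2])
  rho / rho[2]
}

#' Generate a synthetic panoramic film for one sector
#'
#' Places the 24 source spots of one sector at the positions predicted by
#' projecting each source ray onto the measurement cylinder. A spot is a flat
#' core of radius `(collimator/2)/m` (m the source-to-focus over
#' source-to-cylinder distance ratio, i.e. the beam converges between film
#' and focus) with an error-function edge, stretched axially by
#' \eqn{1/\sin\phi} because the beam meets the cylinder obliquely. Optional
#' additive Gaussian noise emulates film/scanner grain.
#'
#' @param array Source array from [build_source_array()].
#' @param collimator `"4"`, `"8"` or `"16"`.
#' @param sector Sector to image (films are taken one sector at a time).
#' @param spot Spot model from [spot_model()].
#' @param dpi Scan resolution; default per [film_dpi()].
#' @param brightness Per-ring relative brightness (default
#'   [ring_brightness()]).
#' @param noise Overrides `spot$noise` when not `NULL`.
#' @param seed Seed for the noise generator.
#' @param x_range,y_range Film extent in mm (arc coordinate relative to the
#'   sector axis; axial coordinate).
#' @return A `gk_film`: list with `intensity` (matrix, rows = axial y,
#'   columns = arc x), `x`, `y` (pixel-centre coordinates mm), `pitch_mm`,
#'   `cylinder_radius`, `collimator`, `sector`, `dpi` and a `truth`
#'   data.frame of generating spot centres.
#' @export
generate_synthetic_film <- function(array, collimator, sector = 1,
                                    spot = spot_model(collimator),
                                    dpi = film_dpi(collimator),
                                    brightness = NULL,
                                    noise = NULL, seed = 1,
                                    x_range = c(-52, 52),
                                    y_range = c(40, 144)) {
  collimator <- as.character(collimator)
  stopifnot(collimator %in% c("4", "8", "16"))
  if (is.null(brightness))
    brightness <- ring_brightness(collimator = collimator)
  if (is.null(noise)) noise <- spot$noise
  R <- attr(array, "cylinder_radius") %||% 113
  src <- array[array$sector == sector, , drop = FALSE]
  if (nrow(src) != 24) stop("sector must contain exactly 24 sources")
  ref_az <- (sector - 1) * 45

  pitch <- 25.4 / dpi
  x <- seq(x_range[1], x_range[2], by = pitch)
  y <- seq(y_range[1], y_range[2], by = pitch)
  img <- matrix(0, nrow = length(y), ncol = length(x))

  ph <- src$phi_deg * pi / 180
  a <- R / sin(ph)                       # focus-to-cylinder distance, mm
  if (any(src$R_s_mm <= a))
    stop("geometry error: source-to-focus distance must exceed the ",
         "focus-to-cylinder distance")
  m <- src$R_s_mm / (src$R_s_mm - a)     # film-to-focus magnification
  rel_az <- ((src$azimuth_deg - ref_az + 180) %% 360) - 180
  truth <- data.frame(
    ring = src$ring, index = src$index,
    x_c = R * (rel_az * pi / 180),
    y_c = R / tan(ph),
    core_mm = (as.numeric(collimator) / 2) / m,
    stretch = 1 / sin(ph),
    amp = spot$peak * brightness[src$ring]
  )

  level <- vector("list", nrow(truth))   # pixels above 1% of each spot's peak
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    half_x <- t$core_mm + 6 * spot$penumbra_sigma
    half_y <- half_x * t$stretch
    jx <- which(x >= t$x_c - half_x & x <= t$x_c + half_x)
    jy <- which(y >= t$y_c - half_y & y <= t$y_c + half_y)
    if (!length(jx) || !length(jy))
      stop("spot for ring ", t$ring, " index ", t$index,
           " falls outside the film")
    dx <- x[jx] - t$x_c
    dy <- (y[jy] - t$y_c) / t$stretch
    u <- sqrt(outer(dy^2, dx^2, `+`))
    val <- t$amp * pnorm((t$core_mm - u) / spot$penumbra_sigma)
    sel <- val > 0.01 * t$amp
    lin <- outer(jy, (jx - 1) * length(y), `+`)
    level[[i]] <- lin[sel]
    img[jy, jx] <- img[jy, jx] + val
  }

  # pairwise non-overlap at the 1% intensity level
  cover <- tabulate(unlist(level), nbins = length(img))
  if (any(cover > 1)) {
    bad <- which(cover > 1)[1]
    pair <- which(vapply(level, function(l) bad %in% l, logical(1)))
    stop(sprintf(
      "geometry error: spots overlap at the 1%% level (ring %d index %d vs ring %d index %d)",
      truth$ring[pair[1]], truth$index[pair[1]],
      truth$ring[pair[2]], truth$index[pair[2]]))
  }

  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(rnorm(length(img), sd = noise * max(truth$amp)),
                        nrow = nrow(img))
    img[img < 0] <- 0
  }

  structure(list(intensity = img, x = x, y = y, pitch_mm = pitch,
                 cylinder_radius = R, collimator = collimator,
                 sector = sector, dpi = dpi, truth = truth),
            class = "gk_film")
}

#' @export
print.gk_film <- function(x, ...) {
  cat(sprintf(
    "<gk_film> %d x %d px, pitch %.4f mm (%g dpi), collimator %s mm, sector %d\n",
    nrow(x$intensity), ncol(x$intensity), x$pitch_mm, x$dpi, x$collimator,
    x$sector))
  invisible(x)
}

#' Perona-Malik anisotropic diffusion of an image
#'
#' Discrete 4-neighbour scheme with exponential conductance
#' \eqn{g(\nabla I) = \exp(-(\nabla I / K)^2)}, step `lambda` and zero-flux
#' (replicated) boundaries, so the total intensity is conserved exactly.
#'
#' @param img Numeric matrix.
#' @param iterations Number of diffusion steps (>= 0).
#' @param conductance Edge-stopping constant K, on the intensity scale.
#' @param lambda Time step (stability requires lambda <= 1/4).
#' @return Smoothed matrix.
#' @export
anisotropic_diffusion <- function(img, iterations = 5, conductance = 0.1,
                                  lambda = 0.2) {
  stopifnot(iterations >= 0, conductance > 0, lambda > 0, lambda <= 0.25)
  if (iterations == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  for (it in seq_len(iterations)) {
    dN <- img[c(1, seq_len(n - 1)), , drop = FALSE] - img
    dS <- img[c(seq_len(n - 1) + 1, n), , drop = FALSE] - img
    dW <- img[, c(1, seq_len(m - 1)), drop = FALSE] - img
    dE <- img[, c(seq_len(m - 1) + 1, m), drop = FALSE] - img
    img <- img + lambda * (
      exp(-(dN / conductance)^2) * dN + exp(-(dS / conductance)^2) * dS +
      exp(-(dW / conductance)^2) * dW + exp(-(dE / conductance)^2) * dE)
  }
  img
}

#' Smooth a film and apply a grayscale morphological opening
#'
#' Anisotropic diffusion (see [anisotropic_diffusion()]) removes film grain
#' without blurring spot edges; the opening (erosion followed by dilation
#' with a disk-shaped structuring element) removes isolated specks smaller
#' than the disk.
#'
#' @param film A `gk_film`.
#' @param iterations,conductance Diffusion parameters.
#' @param disk_radius Radius of the disk structuring element in pixels
#'   (0 skips the opening).
#' @return The processed `gk_film`.
#' @export
smooth_and_open <- function(film, iterations = 5, conductance = 0.1,
                            disk_radius = 2) {
  stopifnot(inherits(film, "gk_film"), disk_radius >= 0)
  img <- anisotropic_diffusion(film$intensity, iterations, conductance)
  if (disk_radius > 0) {
    brush <- EBImage::makeBrush(2 * disk_radius + 1, shape = "disc")
    # EBImage grayscale morphology clamps to [0,1]: rescale around it
    mx <- max(img)
    if (mx > 0) {
      img <- EBImage::dilate(EBImage::erode(img / mx, brush), brush) * mx
    }
  }
  film$intensity <- img
  film$processed <- TRUE
  film
}

#' Write / read a film as 16-bit grayscale PNG plus JSON sidecar
#'
#' The PNG stores intensities scaled to the film maximum; the sidecar keeps
#' the scale, pixel pitch, cylinder radius, sector and collimator so the film
#' can be reconstructed exactly up to 16-bit quantisation.
#'
#' @param film A `gk_film`.
#' @param path PNG path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return [read_film()] returns the `gk_film`.
#' @export
write_film <- function(film, path) {
  mx <- max(film$intensity)
  scl <- if (mx > 0) film$intensity / mx else film$intensity
  png::writePNG(scl, target = path, dpi = film$dpi)
  meta <- list(pitch_mm = film$pitch_mm, cylinder_radius = film$cylinder_radius,
               collimator = film$collimator, sector = film$sector,
               dpi = film$dpi, scale = mx,
               x0 = film$x[1], y0 = film$y[1])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_film
#' @export
read_film <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img <- img * meta$scale
  x <- meta$x0 + (seq_len(ncol(img)) - 1) * meta$pitch_mm
  y <- meta$y0 + (seq_len(nrow(img)) - 1) * meta$pitch_mm
  structure(list(intensity = img, x = x, y = y, pitch_mm = meta$pitch_mm,
                 cylinder_radius = meta$cylinder_radius,
                 collimator = as.character(meta$collimator),
                 sector = meta$sector, dpi = meta$dpi),
            class = "gk_film")
}
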