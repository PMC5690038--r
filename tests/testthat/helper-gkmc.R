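# Shared fixtures, built once per test run and cached.

.gk_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .gk_cache, inherits = FALSE))
    assign(name, force(expr), envir = .gk_cache)
  get(name, envir = .gk_cache, inherits = FALSE)
}

test_array <- function() cached("array", build_source_array())

# noiseless films, raw (no smoothing needed without noise)
test_film_clean <- function(coll)
  cached(paste0("film_clean_", coll),
         generate_synthetic_film(test_array(), coll, noise = 0, seed = 7))

# the realistic pipeline: noisy film -> diffusion -> opening
test_film_processed <- function(coll)
  cached(paste0("film_proc_", coll),
         smooth_and_open(generate_synthetic_film(test_array(), coll,
                                                 seed = 42)))

test_raw_maps <- function()
  cached("raw_maps", {
    m <- lapply(c("4", "8", "16"), function(coll)
      extract_sources(test_film_processed(coll), array = test_array()))
    names(m) <- c("4", "8", "16")
    m
  })

test_masked_maps <- function(threshold = 0.5)
  cached(paste0("masked_", threshold),
         lapply(test_raw_maps(), function(mm)
           lapply(mm, apply_mask_threshold, threshold = threshold)))

test_sphere <- function(radius = 80)
  cached(paste0("sphere_", radius),
         make_phantom("sphere", radius = radius, voxel = 1))

# a small hand-made fluence map for sampler/solid-angle tests
make_test_map <- function(values, pitch = 1, x0 = 0, y0 = 0, R = 113,
                          ring = 1L, sector = 1L, index = 1L,
                          strength = 1) {
  values <- as.matrix(values)
  structure(list(
    values = values,
    x = x0 + (seq_len(ncol(values)) - 1) * pitch,
    y = y0 + (seq_len(nrow(values)) - 1) * pitch,
    pitch = pitch, bixel_area = pitch^2,
    centroid = c(x_s = x0 + (ncol(values) - 1) / 2 * pitch,
                 y_s = y0 + (nrow(values) - 1) / 2 * pitch),
    strength = strength, cylinder_radius = R, sector_ref_deg = 0,
    collimator = "16", mask_threshold = NA_real_,
    tag = list(ring = ring, sector = sector, index = index)),
    class = "gk_fluence_map")
}

# the full calibration (expensive; shared by the acceptance tests)
test_calibration <- function()
  cached("calibration", {
    ref <- reference_output_factors()$rings
    ref$value <- ref$manufacturer
    tune_parameters(ref, test_raw_maps(), test_sphere(80),
                    tolerance = 0.005, seed = 20, n_start = 3e5)
  })
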