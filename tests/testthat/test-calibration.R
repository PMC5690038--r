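test_that("the reference ring output factor is exactly 1 by self-ratio", {
  maps <- test_masked_maps()
  ph <- test_sphere(80)
  ref <- gkmc:::of_central_dose(
    Filter(function(m) m$tag$ring == 2, maps[["16"]]), "16",
    rep(400, 5), ph, n_histories = 2e5, seed = 61)
  # same configuration, same seed -> identical dose, ratio exactly 1
  of <- ring_output_factor("16", 2, maps, ph, n_histories = 2e5, seed = 61,
                           reference = ref)
  expect_identical(of$value, 1)
})

test_that("output factors are invariant under source-weight scaling", {
  maps <- test_masked_maps()
  ph <- test_sphere(80)
  of1 <- ring_output_factor("4", 3, maps, ph, n_histories = 2e5, seed = 62)
  scaled <- lapply(maps, function(mm) lapply(mm, function(m) {
    m$strength <- m$strength * 2
    m
  }))
  of2 <- ring_output_factor("4", 3, scaled, ph, n_histories = 2e5, seed = 62)
  expect_equal(of1$value, of2$value, tolerance = 1e-12)
})

test_that("collimator output factors combine rings with source counts", {
  # identical ring factors for c and the reference give exactly 1
  f <- matrix(0.7, 5, 2, dimnames = list(NULL, c("8", "16")))
  expect_equal(unname(collimator_output_factor(f, c(5, 5, 5, 5, 4))["8"]), 1)

  # the printed per-ring values reproduce the printed totals
  ref <- reference_output_factors()
  rg <- ref$rings
  m <- sapply(c("4", "8", "16"), function(cl)
    rg$calculated[rg$collimator == cl][order(rg$ring[rg$collimator == cl])])
  fc <- collimator_output_factor(m, derive_ring_multiplicities())
  expect_lt(abs(fc[["4"]] - 0.814), 0.002)
  expect_lt(abs(fc[["8"]] - 0.901), 0.002)
  expect_equal(fc[["16"]], 1)

  # missing ring entry errors
  df <- data.frame(collimator = "8", ring = 1:4, value = 0.9)
  expect_error(collimator_output_factor(df), "missing ring")
})

test_that("solid angle follows the closed form and a cap oracle", {
  # 10 x 10 bixels of 1 mm pitch at the equator: S = 100 mm^2
  m <- make_test_map(matrix(1, 10, 10), pitch = 1, x0 = -4.5, y0 = -4.5)
  # centroid at y_s = 0 -> theta 90 deg, so R_s - L = 100 -> Omega = 0.01
  expect_equal(solid_angle(list(m), R_s = 213), 100 / 100^2,
               tolerance = 1e-12)
  # additive over sources / linear in area
  expect_equal(solid_angle(list(m, m), R_s = 213), 0.02, tolerance = 1e-12)

  # small-aperture limit vs brute-force integration over the patch
  sm <- make_test_map(matrix(1, 4, 4), pitch = 0.5, x0 = -0.75, y0 = -0.75)
  d <- 300 - 113   # source-to-cylinder distance along the central ray
  omega <- solid_angle(list(sm), R_s = 300)
  # oracle: sum over fine sub-patches of cos(beta) dA / r^2 from the source
  src <- c(300, 0, 0)
  gx <- seq(-0.9875, 0.9875, by = 0.025)
  acc <- 0
  for (xs in gx) for (ys in gx) {
    p <- film_to_cylinder(xs, ys, 113)[1, ]
    v <- src - p
    r2 <- sum(v^2)
    nrm <- c(p[1], p[2], 0) / 113
    acc <- acc + abs(sum(v * nrm)) / sqrt(r2) * 0.025^2 / r2
  }
  expect_lt(abs(omega - (2^2) / d^2) / omega, 0.01)
  expect_lt(abs(acc - omega) / omega, 0.01)

  # nonpositive denominator errors
  expect_error(solid_angle(list(m), R_s = 100), "geometry error")
})

test_that("the calibration factor inverts the absolute-dose relation", {
  # the calibration prescription: 5 Gy with unit factors gives M = 5 Omega
  expect_equal(calibration_factor(5, 1, 1, 1, Omega = 2), 10)
  # round trip: forward relation returns D_m exactly
  M <- calibration_factor(D_m = 3.2, D_r = 2.5, T_min = 1.7, D_MC = 4e-8,
                          Omega = 0.37)
  expect_equal(M / 0.37 * 2.5 * 1.7 * 4e-8, 3.2, tolerance = 1e-12)
  # inverse proportionality to D_MC
  expect_equal(calibration_factor(3.2, 2.5, 1.7, 8e-8, 0.37), M / 2,
               tolerance = 1e-12)
  expect_error(calibration_factor(0, 1, 1, 1, 1), "positive")
  expect_error(calibration_factor(5, 1, -1, 1, 1), "positive")

  # absolute_dose applies M/Omega * D_r to a grid
  g <- structure(list(dose = array(2, c(2, 2, 2))), class = "gk_dose_grid")
  out <- absolute_dose(g, M = 6, Omega = 3, D_r = 2)
  expect_equal(out$dose, array(8, c(2, 2, 2)))
})

test_that("a zero-iteration tuning budget returns the initial parameters", {
  ref <- reference_output_factors()$rings
  ref$value <- ref$manufacturer
  cal <- suppressWarnings(
    tune_parameters(ref, test_raw_maps(), test_sphere(80),
                    tolerance = 0.05, budget = 0, seed = 5, n_start = 5e4))
  expect_equal(unname(cal$R_s), matrix(400, 3, 5), ignore_attr = TRUE)
  expect_equal(unname(cal$thresholds), c(0.5, 0.5, 0.5))
  expect_equal(cal$line_searches, 0)
  expect_true(all(is.finite(cal$residuals)))
})
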