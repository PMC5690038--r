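test_that("extraction finds 24 sources with accurate weighted centroids", {
  for (coll in c("4", "8", "16")) {
    film <- test_film_processed(coll)
    maps <- extract_sources(film, array = test_array())
    expect_length(maps, 24)
    truth <- generate_synthetic_film(test_array(), coll, seed = 42)$truth
    truth <- truth[order(truth$index), ]
    cen <- t(vapply(maps, `[[`, numeric(2), "centroid"))
    expect_lt(max(abs(cen[, 1] - truth$x_c)), 0.05)
    expect_lt(max(abs(cen[, 2] - truth$y_c)), 0.05)
    expect_true(all(vapply(maps, function(m) max(m$values), numeric(1)) == 1))
    expect_true(all(vapply(maps, function(m) m$bixel_area, numeric(1)) ==
                      film$pitch_mm^2))
  }
})

test_that("merged spots raise a segmentation error reporting the count", {
  film <- test_film_processed("16")
  # draw a bright bridge between the two lowest spots to merge them
  truth <- generate_synthetic_film(test_array(), "16", seed = 42)$truth
  o <- order(truth$y_c, truth$x_c)
  a <- truth[o[1], ]; b <- truth[o[2], ]
  n <- 200
  xs <- seq(a$x_c, b$x_c, length.out = n)
  ys <- seq(a$y_c, b$y_c, length.out = n)
  for (k in seq_len(n)) {
    i <- which.min(abs(film$y - ys[k]))
    j <- which.min(abs(film$x - xs[k]))
    film$intensity[i, j] <- 1
  }
  expect_error(extract_sources(film, array = test_array()), "23")
})

test_that("film-to-cylinder mapping satisfies the closed-form examples", {
  R <- 113
  expect_equal(film_to_cylinder(0, 0, R)[1, ], c(x = R, y = 0, z = 0),
               tolerance = 1e-12)
  expect_equal(film_to_cylinder(pi * R / 2, 5, R)[1, ],
               c(x = 0, y = R, z = 5), tolerance = 1e-12)
  # all mapped points lie on the cylinder
  xs <- seq(-pi * R, pi * R, length.out = 101)
  p <- film_to_cylinder(xs, rep(2, 101), R)
  expect_equal(sqrt(p[, 1]^2 + p[, 2]^2), rep(R, 101), tolerance = 1e-9)
  # arc-length isometry at fixed y: surface distance equals film distance
  p2 <- film_to_cylinder(c(10, 25), c(4, 4), R)
  ang <- acos(sum(p2[1, 1:2] * p2[2, 1:2]) / R^2)
  expect_equal(R * ang, 15, tolerance = 1e-9)
  expect_error(film_to_cylinder(pi * R + 1, 0, R), "wrap")
})

test_that("centroid-to-angle inversion recovers the source geometry", {
  arr <- test_array()
  for (coll in c("4", "8", "16")) {
    maps <- extract_sources(test_film_processed(coll), array = arr)
    ang <- do.call(rbind, lapply(maps, centroid_to_angles))
    s1 <- arr[arr$sector == 1, ]
    s1 <- s1[order(s1$index), ]
    daz <- abs((ang$azimuth_deg - s1$azimuth_deg + 180) %% 360 - 180)
    expect_lt(max(daz), 0.2)
    z_pred <- 113 / tan(s1$phi_deg * pi / 180)
    expect_lt(max(abs(ang$z_mm - z_pred)), 0.14)
  }
  # x_s = 0 maps to the sector reference azimuth
  expect_equal(centroid_to_angles(c(0, 73), R = 113,
                                  sector_ref_deg = 45)$azimuth_deg, 45)
})

test_that("mask threshold saturates the core and is monotone", {
  maps <- test_raw_maps()[["16"]]
  m <- maps[[5]]
  m0 <- apply_mask_threshold(m, 0)
  expect_true(all(m0$values[m$values > 0] == 1))
  cores <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t)
    sum(apply_mask_threshold(m, t)$values == 1), numeric(1))
  expect_true(all(diff(cores) <= 0))
  # integrated fluence nondecreasing as the threshold decreases
  masses <- vapply(c(0.8, 0.5, 0.2, 0), function(t)
    fluence_mass(apply_mask_threshold(m, t)), numeric(1))
  expect_true(all(diff(masses) >= 0))
  expect_error(apply_mask_threshold(m, 1), "threshold")
  dim_map <- m
  dim_map$values <- m$values * 0.8     # peak below the threshold
  expect_error(apply_mask_threshold(dim_map, 0.9), "empty core")

  # linear-ramp map: core fraction above 0.5 equals the analytic level set
  ramp <- make_test_map(matrix(rep(seq(0.01, 1, length.out = 100), 10),
                               10, 100, byrow = TRUE))
  mr <- apply_mask_threshold(ramp, 0.5)
  frac <- mean(mr$values == 1)
  analytic <- mean(seq(0.01, 1, length.out = 100) > 0.5)
  expect_equal(frac, analytic, tolerance = 1e-12)
})

test_that("particle sampling follows the fluence distribution", {
  # single-bixel map: always that bixel
  one <- make_test_map(matrix(c(0, 0, 0, 1), 2, 2))
  cfg1 <- build_shot_fluence(gk_shot(c(0, 0, 0), rep("16", 8), 2),
                             list("16" = list(one)))
  s1 <- sample_particle(cfg1, 200, seed = 3)
  expect_true(all(s1$bixel == 4))
  expect_true(all(s1$weight == 2))

  # two bixels 1:3 within binomial error at n = 1e5
  two <- make_test_map(matrix(c(1, 3), 1, 2))
  cfg2 <- build_shot_fluence(gk_shot(c(0, 0, 0), c("16", rep("blocked", 7)), 1),
                             list("16" = list(two)))
  s2 <- sample_particle(cfg2, 1e5, seed = 4)
  p <- mean(s2$bixel == 2)
  expect_lt(abs(p - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))

  # chi-square vs normalised intensities at alpha = 0.01
  set.seed(8)
  vals <- matrix(runif(12, 0.2, 2), 3, 4)
  m <- make_test_map(vals)
  cfg3 <- build_shot_fluence(gk_shot(c(0, 0, 0), c("16", rep("blocked", 7)), 1),
                             list("16" = list(m)))
  s3 <- sample_particle(cfg3, 1e5, seed = 5)
  obs <- tabulate(s3$bixel, nbins = 12)
  expected <- as.numeric(vals) / sum(vals)
  pval <- suppressWarnings(chisq.test(obs, p = expected)$p.value)
  expect_gt(pval, 0.01)

  # every sampled ray passes through the tagged source point
  maps <- test_masked_maps()
  cfg <- build_shot_fluence(gk_shot(c(5, 5, 5), rep("8", 8), 1), maps)
  sp <- sample_particle(cfg, 500, seed = 6)
  ins <- cfg$instances
  for (k in seq_len(50)) {
    i <- sp$instance[k]
    s <- c(ins$sx[i], ins$sy[i], ins$sz[i])
    p <- c(sp$x[k], sp$y[k], sp$z[k])
    u <- c(sp$ux[k], sp$uy[k], sp$uz[k])
    v <- p - s
    cosang <- sum(v * u) / sqrt(sum(v^2))
    expect_gt(cosang, 1 - 1e-12)
  }

  # zero-mass fluence errors
  zero <- make_test_map(matrix(0, 2, 2))
  expect_error(build_shot_fluence(gk_shot(c(0, 0, 0), c("16", rep("blocked", 7)), 1),
                                  list("16" = list(zero))), "zero-mass")
})
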