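test_that("source array satisfies the Perfexion arrangement invariants", {
  arr <- test_array()
  expect_equal(nrow(arr), 192)
  expect_true(all(table(arr$sector) == 24))
  expect_true(all(table(arr$ring, arr$sector) ==
                    matrix(c(5, 5, 5, 5, 4), 5, 8)))
  # all sources of one ring share phi and R_s
  for (r in 1:5) {
    expect_equal(length(unique(arr$phi_deg[arr$ring == r])), 1)
    expect_equal(length(unique(arr$R_s_mm[arr$ring == r])), 1)
  }
  # sector k azimuths are sector 1 azimuths rotated by (k-1)*45 degrees
  az1 <- sort(arr$azimuth_deg[arr$sector == 1] %% 360)
  for (k in 2:8) {
    azk <- sort((arr$azimuth_deg[arr$sector == k] - (k - 1) * 45) %% 360)
    expect_equal(azk, az1, tolerance = 1e-12)
  }
  # positions sit at distance R_s from the focus
  pos <- source_positions(arr)
  expect_equal(sqrt(rowSums(pos^2)), arr$R_s_mm, tolerance = 1e-12)
})

test_that("invalid ring geometry tables are rejected", {
  geom <- pfx_ring_geometry()
  bad <- geom
  bad$multiplicity <- c(5, 5, 5, 5, 5)       # sums to 25
  expect_error(build_source_array(bad), "sum to 25")
  bad <- geom
  bad$R_s_mm[2] <- -1
  expect_error(build_source_array(bad), "nonpositive")
  bad <- geom
  bad$phi_deg[1] <- 190
  expect_error(build_source_array(bad), "phi")
})

test_that("derived ring multiplicities reproduce the reference totals", {
  mult <- derive_ring_multiplicities()
  expect_equal(as.integer(mult), c(5L, 5L, 5L, 5L, 4L))
  wt <- attr(mult, "weighted_totals")
  ref <- reference_output_factors()
  expect_lt(abs(wt[["4"]] - ref$totals$calculated[ref$totals$collimator == "4"]),
            0.002)
  expect_lt(abs(wt[["8"]] - ref$totals$calculated[ref$totals$collimator == "8"]),
            0.002)
  # a grossly uneven vector is flagged by the same consistency check
  rg <- ref$rings
  f <- function(cl) rg$calculated[rg$collimator == cl][order(rg$ring[rg$collimator == cl])]
  bad <- c(20, 1, 1, 1, 1)
  w4 <- sum(bad * f("4")) / sum(bad * f("16"))
  w8 <- sum(bad * f("8")) / sum(bad * f("16"))
  expect_gt(max(abs(w4 - 0.814), abs(w8 - 0.901)), 0.002)
})

test_that("shot_transform is a rigid translation that drops blocked sectors", {
  arr <- test_array()
  s0 <- gk_shot(c(0, 0, 0), rep("16", 8), 1)
  t0 <- shot_transform(s0, arr)
  expect_equal(cbind(t0$x, t0$y, t0$z), unname(source_positions(arr)),
               tolerance = 1e-12, ignore_attr = TRUE)

  s1 <- gk_shot(c(10, 0, 0), rep("16", 8), 1)
  t1 <- shot_transform(s1, arr)
  expect_equal(t1$x - t0$x, rep(10, 192), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(t1$y, t0$y, tolerance = 1e-12)
  expect_equal(t1$z, t0$z, tolerance = 1e-12)

  sb <- gk_shot(c(0, 0, 0), rep("blocked", 8), 1)
  expect_warning(tb <- shot_transform(sb, arr), "blocked")
  expect_equal(nrow(tb), 0)

  sm <- gk_shot(c(0, 0, 0), c("4", "blocked", "8", "blocked", "16",
                              "blocked", "4", "blocked"), 1)
  tm <- shot_transform(sm, arr)
  expect_setequal(unique(tm$sector), c(1, 3, 5, 7))
  expect_equal(nrow(tm), 96)

  ph <- test_sphere(80)
  expect_warning(shot_transform(gk_shot(c(500, 0, 0), rep("16", 8), 1),
                                arr, ph), "outside")
})

test_that("rays through fluence-map centres pass through the shot focus", {
  maps <- test_masked_maps()
  focus <- c(12.5, -7.25, 4)
  shot <- gk_shot(focus, c("4", "8", "16", "4", "8", "16", "4", "8"), 1.5)
  cfg <- build_shot_fluence(shot, maps)
  ins <- cfg$instances
  for (i in seq_len(nrow(ins))) {
    m <- cfg$maps[[ins$map_id[i]]]
    # centroid of the map in world coordinates
    mm <- maps[[ins$collimator[i]]]
    cen <- Filter(function(q) q$tag$index == ins$index[i], mm)[[1]]$centroid
    p <- film_to_cylinder(cen[1], cen[2], m$R,
                          sector_ref_deg = ins$rot_deg[i])[1, ] +
      c(ins$tx[i], ins$ty[i], ins$tz[i])
    s <- c(ins$sx[i], ins$sy[i], ins$sz[i])
    u <- (p - s) / sqrt(sum((p - s)^2))
    d <- focus - s
    dist <- sqrt(sum((d - sum(d * u) * u)^2))   # focus-to-ray distance
    expect_lt(dist, 1e-9)
  }
})
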