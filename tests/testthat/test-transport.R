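# helpers to talk to the kernel directly
kernel_xsec <- function() gkmc:::xsec_for_kernel()
kernel_phantom <- function(ph)
  list(density = as.numeric(ph$density), dims = as.integer(dim(ph$density)),
       voxel = ph$voxel, origin = ph$origin)

test_that("free-path sampling and process selection match the attenuation table", {
  # homogeneous water column, 2000 mm deep (escape fraction ~ e^-12.6)
  dens <- array(1, dim = c(8, 8, 42))
  ph <- structure(list(density = dens, voxel = 50,
                       origin = c(-175, -175, -1025)), class = "gk_phantom")
  tb <- water_xsec_table()
  mu125 <- exp(approx(log(tb$energy), log(tb$mu_total), xout = log(1.25))$y)
  res <- gkmc:::cpp_first_interaction(1.25, 1e5, 17, kernel_xsec(),
                                      kernel_phantom(ph),
                                      c(0, 0, -1020), c(0, 0, 1))
  d <- res$depth_mm[res$depth_mm > 0]
  expect_gt(length(d), 0.99e5)
  mfp_mm <- 10 / mu125
  expect_lt(abs(mean(d) - mfp_mm) / mfp_mm, 0.01)
  # process fractions at 1.25 MeV: overwhelmingly Compton, pair possible
  pr <- res$process[res$process > 0]
  fC <- exp(approx(log(tb$energy), log(tb$mu_compton), xout = log(1.25))$y) / mu125
  expect_lt(abs(mean(pr == 1) - fC), 0.001)
  expect_true(all(pr %in% c(1, 2, 3)))

  # at 60 keV the photoelectric fraction is a few permille and measurable
  res2 <- gkmc:::cpp_first_interaction(0.06, 1e5, 18, kernel_xsec(),
                                       kernel_phantom(ph),
                                       c(0, 0, -1020), c(0, 0, 1))
  pr2 <- res2$process[res2$process > 0]
  mu06C <- exp(approx(log(tb$energy), log(tb$mu_compton), xout = log(0.06))$y)
  mu06P <- exp(approx(log(tb$energy), log(tb$mu_photo), xout = log(0.06))$y)
  fP <- mu06P / (mu06C + mu06P)
  obs <- mean(pr2 == 2)
  expect_lt(abs(obs - fP), 3 * sqrt(fP * (1 - fP) / length(pr2)))
  expect_true(all(pr2 != 3))   # no pair production below threshold
})

test_that("photons cross a vacuum phantom without interacting", {
  dens <- array(0, dim = c(20, 20, 20))
  ph <- structure(list(density = dens, voxel = 5, origin = c(-47.5, -47.5, -47.5)),
                  class = "gk_phantom")
  res <- gkmc:::cpp_first_interaction(1.25, 1000, 3, kernel_xsec(),
                                      kernel_phantom(ph),
                                      c(0, 0, -200), c(0, 0, 1))
  expect_true(all(res$process == 0))
})

test_that("Compton kinematics reproduce the closed-form limits", {
  # theta = 0 leaves the photon energy unchanged (formula check)
  E <- 1.33
  a <- E / 0.510998928
  Eprime <- function(ct) E / (1 + a * (1 - ct))
  expect_equal(Eprime(1), E)
  # backscatter gives the printed Compton edge to the electron
  expect_equal(E - Eprime(-1), compton_edge(E), tolerance = 1e-12)

  s <- gkmc:::cpp_sample_compton(1.33, 2e5, 21)
  elec <- 1.33 - s[, "energy_scattered"]
  expect_lte(max(elec), compton_edge(1.33) + 1e-12)
  expect_gt(max(elec), compton_edge(1.33) - 0.01)
  expect_true(all(s[, "cos_theta"] >= -1 & s[, "cos_theta"] <= 1))
  # energies and angles tied by the Compton relation
  expect_equal(s[, "energy_scattered"], Eprime(s[, "cos_theta"]),
               tolerance = 1e-9)
})

test_that("electron deposition conserves energy within CSDA range bounds", {
  # fine grid: 0.1 mm voxels
  dens <- array(1, dim = c(101, 101, 101))
  ph <- list(density = as.numeric(dens), dims = c(101L, 101L, 101L),
             voxel = 0.1, origin = c(-5, -5, -5))
  # 100 keV electron: range 0.143 mm -> deposits within ~2 voxels
  tr <- gkmc:::cpp_electron_track(0.1, c(0, 0, 0), c(1, 0, 0), ph,
                                  kernel_xsec())
  expect_equal(tr$deposited + tr$escaped, 0.1, tolerance = 1e-9)
  expect_equal(tr$escaped, 0)
  ijk <- t(vapply(tr$voxel, function(v) {
    v0 <- v - 1
    c(v0 %% 101, (v0 %/% 101) %% 101, v0 %/% (101 * 101))
  }, numeric(3)))
  d_mm <- sqrt(rowSums((sweep(ijk, 2, c(50, 50, 50)))^2)) * 0.1
  expect_lte(max(d_mm), 0.25)

  # 1 MeV electron: penetration bounded by the CSDA range (~4.4 mm)
  tr1 <- gkmc:::cpp_electron_track(1.0, c(0, 0, 0), c(0, 0, 1), ph,
                                   kernel_xsec())
  expect_equal(tr1$deposited + tr1$escaped, 1.0, tolerance = 1e-9)
  ijk1 <- t(vapply(tr1$voxel, function(v) {
    v0 <- v - 1
    c(v0 %% 101, (v0 %/% 101) %% 101, v0 %/% (101 * 101))
  }, numeric(3)))
  d1 <- sqrt(rowSums((sweep(ijk1, 2, c(50, 50, 50)))^2)) * 0.1
  expect_lte(max(d1), 10 * csda_range(1.0) + 0.2)
  expect_gt(max(d1), 2)   # it does travel several mm
})

test_that("dose runs conserve energy and respect the emission bound", {
  maps <- test_masked_maps()
  ph <- test_sphere(40)
  cfg <- build_shot_fluence(gk_shot(c(0, 0, 0), rep("16", 8), 1), maps)
  gr <- run_simulation(cfg, ph, n_histories = 5e4, seed = 33, batches = 5)
  acct <- gr$accounting
  expect_equal(acct$emitted_MeV, acct$deposited_MeV + acct$escaped_MeV,
               tolerance = 1e-9)
  expect_lte(acct$deposited_MeV, acct$emitted_MeV)
  expect_gt(acct$deposited_MeV, 0)
  # mean emitted energy matches the spectrum mean
  expect_equal(acct$emitted_MeV, mean_energy(default_spectrum()),
               tolerance = 0.01)
})

test_that("identical seed and batch partition give bitwise-identical grids", {
  maps <- test_masked_maps()
  ph <- test_sphere(40)
  cfg <- build_shot_fluence(gk_shot(c(0, 0, 0), rep("4", 8), 1), maps)
  g1 <- run_simulation(cfg, ph, n_histories = 2e4, seed = 12, batches = 4)
  g2 <- run_simulation(cfg, ph, n_histories = 2e4, seed = 12, batches = 4)
  expect_identical(g1$dose, g2$dose)
  expect_identical(g1$relerr, g2$relerr)
  g3 <- run_simulation(cfg, ph, n_histories = 2e4, seed = 13, batches = 4)
  expect_false(identical(g1$dose, g3$dose))
})

test_that("invalid simulation requests are rejected", {
  maps <- test_masked_maps()
  ph <- test_sphere(40)
  cfg <- build_shot_fluence(gk_shot(c(0, 0, 0), rep("16", 8), 1), maps)
  expect_error(run_simulation(cfg, ph, n_histories = 0, seed = 1),
               "zero histories")
  expect_error(run_simulation(cfg, ph, n_histories = 3, seed = 1,
                              batches = 10), "batches")
})

test_that("dose from the 8-sector array is symmetric under 90-degree rotation", {
  # 8 sectors spaced 45 degrees: the expected dose pattern has exact 45-degree
  # periodicity about the cylinder axis, so a 90-degree grid rotation must
  # agree within statistics
  maps <- test_masked_maps()
  ph <- test_sphere(40)
  cfg <- build_shot_fluence(gk_shot(c(0, 0, 0), rep("16", 8), 1), maps)
  gr <- run_simulation(cfg, ph, n_histories = 6e5, seed = 44, batches = 10)
  d <- gr$dose
  rot <- aperm(d, c(2, 1, 3))[dim(d)[2]:1, , ]   # 90-degree rotation about z
  hot <- d >= 0.5 * max(d)
  rel <- 2 * abs(d[hot] - rot[hot]) / (d[hot] + rot[hot])
  err <- gr$relerr[hot]
  # median paired difference is within a few combined standard errors
  expect_lt(median(rel), 3 * sqrt(2) * median(err))
})
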