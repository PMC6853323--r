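test_that("ballistic tracks are straight lines with exact step geometry", {
  tt <- simulate_tracks(track_sim_spec(1, 50, model = "ballistic",
                                       step_um = 2, seed = 1))
  pos <- split_tracks(tt)[[1]]$pos
  expect_equal(compute_track_displacement(pos), 98)  # 49 steps x 2 um
  expect_equal(unique(diff(pos[, 1])), 2)
  expect_equal(max(abs(pos[, 2:3])), 0)
})

test_that("fbm increment variance follows sigma^2 * k^(2H) at every lag", {
  for (H in c(0.3, 0.5, 0.7)) {
    tt <- simulate_tracks(track_sim_spec(3500, 4, model = "fbm", hurst = H,
                                         step_um = 0.8, seed = 100 + H * 10))
    tracks <- split_tracks(tt)
    for (k in 1:3) {
      # one increment per track per coordinate: independent samples
      inc <- unlist(lapply(tracks, function(tr) tr$pos[1 + k, ] - tr$pos[1, ]))
      n <- length(inc)
      expect_gt(n, 1e4)
      target <- 0.8^2 * k^(2 * H)
      se <- target * sqrt(2 / (n - 1))
      expect_lt(abs(var(inc) - target), 3 * se)
    }
  }
})

test_that("identical spec and seed give bit-identical simulator output", {
  s <- track_sim_spec(5, 20, model = "fbm", seed = 7)
  expect_identical(simulate_tracks(s), simulate_tracks(s))
  sn <- network_sim_spec(10, 0.5, n_fibers = 10, seed = 7)
  expect_identical(simulate_network(sn), simulate_network(sn))
  sa <- afm_sim_spec(100, noise_nN = 0.02, n_samples = 64L, seed = 7)
  expect_identical(simulate_force_bundle(sa), simulate_force_bundle(sa))
})

test_that("confined walks stay in the box and their MSD saturates", {
  box <- 10
  tt <- simulate_tracks(track_sim_spec(20, 50, model = "confined_box",
                                       box_um = box, step_um = 2,
                                       start = rep(box / 2, 3), seed = 3))
  expect_true(all(tt$x_um >= 0 & tt$x_um <= box))
  expect_true(all(tt$z_um >= 0 & tt$z_um <= box))
  for (tr in split_tracks(tt)) {
    msd <- compute_msd(tr$pos, 49)
    expect_lte(max(msd$msd_um2), 3 * box^2)  # diagonal bound
  }
})

test_that("simulator specs reject invalid model parameters", {
  expect_error(track_sim_spec(1, model = "fbm", hurst = 1.2),
               class = "migr3d_validation_error")
  expect_error(track_sim_spec(1, model = "persistent", persistence = 1),
               class = "migr3d_validation_error")
  expect_error(track_sim_spec(1, step_um = 0),
               class = "migr3d_validation_error")
  expect_error(network_sim_spec(10, voxel_um = 0.5, fiber_radius_um = 0.2),
               class = "migr3d_validation_error")
  expect_error(afm_sim_spec(-5), class = "migr3d_validation_error")
  expect_error(afm_sim_spec(100, poisson = 0.7),
               class = "migr3d_validation_error")
})

test_that("fiber networks rasterize lines to the declared radius", {
  # empty network
  v0 <- simulate_network(network_sim_spec(8, 0.5, n_fibers = 0, seed = 1))
  expect_equal(sum(v0$data), 0)
  expect_true(v0$binary)

  # parallel-pairs fibers are axis-aligned cylinders of the declared
  # radius: the z-extent of a wall equals the fiber diameter +- 1 voxel
  h <- 0.5; r <- 1.5
  vp <- simulate_network(network_sim_spec(c(16, 8, 8), h,
                                          placement = "parallel_pairs",
                                          pair_spacing_um = 8,
                                          fiber_radius_um = r))
  # profile along z through a wall-center y position (first wall at y = r)
  jy <- max(1L, round(r / h))
  prof <- vp$data[, jy, 1]
  runs <- rle(prof)
  wall_vox <- runs$lengths[runs$values == 1]
  expect_true(all(abs(wall_vox * h - 2 * r) <= h + 1e-9))

  # volume fraction rises monotonically with fiber count
  fracs <- vapply(c(5, 10, 20, 40), function(nf) {
    mean(simulate_network(network_sim_spec(12, 0.5, n_fibers = nf,
                                           fiber_radius_um = 0.8,
                                           seed = 9))$data)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("synthetic force curves follow the pyramid Hertz form", {
  # E = 0 limit: flat curve
  b0 <- simulate_force_bundle(afm_sim_spec(1e-12, n_samples = 64L))
  expect_lt(max(abs(bundle_curve(b0, 1, 1)$force_nN)), 1e-9)
  # doubling E doubles the force at fixed piezo position (stiff lever)
  stiff <- 1e5  # N/m: deflection correction negligible
  f1 <- bundle_curve(simulate_force_bundle(
    afm_sim_spec(100, n_samples = 64L,
                 spring_constant_N_per_m = stiff)), 1, 1)$force_nN
  f2 <- bundle_curve(simulate_force_bundle(
    afm_sim_spec(200, n_samples = 64L,
                 spring_constant_N_per_m = stiff)), 1, 1)$force_nN
  expect_equal(f2, 2 * f1, tolerance = 1e-6)
  # and the generated force solves the deflection-corrected implicit form
  b <- simulate_force_bundle(afm_sim_spec(500, n_samples = 128L))
  cv <- bundle_curve(b, 1, 1)
  a <- 1e-3 * hertz_pyramid_coefficient() * 500
  k <- 0.03 * 1000
  s <- pmax(cv$distance_um - 2, 0)
  expect_equal(cv$force_nN, a * (s - cv$force_nN / k)^2, tolerance = 1e-9)
})
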