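test_that("MSD matches hand-enumerated and closed-form values", {
  # stationary
  expect_equal(compute_msd(matrix(1, 5, 3), 3)$msd_um2, rep(0, 3))
  # hand-enumerated toy track
  msd <- compute_msd(toy_track_pos(), 2, 1200)
  expect_equal(msd$msd_um2, c(1, 2))
  expect_equal(msd$n_pairs, c(4, 3))
  expect_equal(msd$tau_s, c(1200, 2400))
  # ballistic closed form: msd_k = (k l)^2
  l <- 1.7
  pos <- cbind(seq(0, by = l, length.out = 20), 0, 0)
  expect_equal(compute_msd(pos, 6)$msd_um2, (1:6 * l)^2)
  # errors
  expect_error(compute_msd(pos, 25), class = "migr3d_length_error")
  bad <- make_track_df("a", pos[1:5, ])
  bad$frame <- c(0, 1, 2, 4, 8)
  bad$time_s <- bad$frame * 1200
  expect_error(compute_msd(track_table(bad), 2),
               class = "migr3d_validation_error")
})

test_that("anomalous fit recovers exact power laws and flags degeneracy", {
  tau <- (1:6) * 1200
  m <- structure(data.frame(lag = 1:6, tau_s = tau, msd_um2 = tau,
                            n_pairs = 50 - 1:6),
                 class = c("msd_curve", "data.frame"))
  fit <- fit_anomalous(m, 5)
  expect_equal(fit$alpha, 1, tolerance = 1e-12)
  expect_equal(fit$D_um2_per_s_alpha, 1, tolerance = 1e-10)
  # ballistic: msd = (v tau)^2 -> alpha 2, D = v^2
  v <- 3.2e-3
  m$msd_um2 <- (v * tau)^2
  fit2 <- fit_anomalous(m, 5)
  expect_equal(fit2$alpha, 2, tolerance = 1e-12)
  expect_equal(fit2$D_um2_per_s_alpha, v^2, tolerance = 1e-10)
  # nonlinear route agrees on exact power laws
  fit3 <- fit_anomalous(m, 5, method = "nls")
  expect_equal(fit3$alpha, 2, tolerance = 1e-6)
  # stationary track: degenerate, not -Inf
  m$msd_um2 <- rep(0, 6)
  expect_error(fit_anomalous(m, 5), class = "migr3d_degenerate_input")
})

test_that("speed is the root first-lag MSD over the frame time, in nm/s", {
  expect_equal(compute_speed(matrix(0, 5, 3)), 0)
  # 3.84 um per 1200-s frame = 3.2 nm/s, the fast-cell threshold scale
  pos <- cbind(seq(0, by = 3.84, length.out = 10), 0, 0)
  expect_equal(compute_speed(pos, 1200), 3.2)
  expect_equal(compute_speed(toy_track_pos(), 1200), 1000 / 1200)
  expect_error(compute_speed(matrix(0, 1, 3)), class = "migr3d_length_error")
})

test_that("turning angles capture straight motion, backtracking and isotropy", {
  straight <- cbind(1:5, 0, 0)
  expect_equal(compute_turning_angles(straight), rep(0, 3))
  back <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  expect_equal(compute_turning_angles(back), 180)
  # zero-length steps are skipped, not propagated as NaN
  pause <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(compute_turning_angles(pause), numeric(0))
  expect_error(compute_turning_angles(matrix(3, 4, 3)),
               class = "migr3d_degenerate_input")
  # isotropic random walk: cos(angle) uniform on [-1, 1]
  withr::with_seed(99, {
    pos <- random_walk_pos(10001)
    ang <- compute_turning_angles(pos)
    ks <- stats::ks.test(cos(ang * pi / 180), "punif", -1, 1)
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("track displacement is the end-to-end distance", {
  loop <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0), c(0, 0, 0))
  expect_equal(compute_track_displacement(loop), 0)
  expect_equal(compute_track_displacement(toy_track_pos()), sqrt(6))
  pos <- cbind(seq(0, by = 2, length.out = 50), 0, 0)
  expect_equal(compute_track_displacement(pos), 98)
})

test_that("speed, MSD and displacement obey their definitional relations", {
  withr::with_seed(5, {
    for (i in 1:20) {
      pos <- random_walk_pos(30, sd = runif(1, 0.1, 3))
      dt <- runif(1, 100, 2000)
      # speed x dt = sqrt(msd_1)
      expect_equal(compute_speed(pos, dt) * dt / 1000,
                   sqrt(compute_msd(pos, 1, dt)$msd_um2[1]))
      # net displacement bounded by total path length
      path <- sum(sqrt(rowSums(diff(pos)^2)))
      expect_lte(compute_track_displacement(pos), path + 1e-12)
    }
  })
})

test_that("features are invariant under rigid motion of the track", {
  withr::with_seed(17, {
    pos <- random_walk_pos(40, sd = 1.5)
    Q <- random_rotation()
    moved <- sweep(pos %*% t(Q), 2, c(13, -4, 7), `+`)
    expect_equal(compute_speed(moved), compute_speed(pos),
                 tolerance = 1e-9)
    expect_equal(compute_msd(moved, 5)$msd_um2,
                 compute_msd(pos, 5)$msd_um2, tolerance = 1e-9)
    expect_equal(compute_turning_angles(moved), compute_turning_angles(pos),
                 tolerance = 1e-9)
    expect_equal(compute_track_displacement(moved),
                 compute_track_displacement(pos), tolerance = 1e-9)
  })
})

test_that("per-track feature tables carry labels and handle stationary tracks", {
  tt <- rbind(make_track_df("m1", toy_track_pos(), condition = "LT",
                            phenotype = "A1"),
              make_track_df("m2", matrix(2, 5, 3), condition = "HT",
                            phenotype = "R"))
  feats <- track_features(track_table(tt), run_config(n_fit_lags = 2L))
  expect_equal(nrow(feats), 2L)
  m1 <- feats[feats$track_id == "m1", ]
  expect_equal(m1$speed_nm_s, 1000 / 1200)
  expect_equal(m1$phenotype, "A1")
  m2 <- feats[feats$track_id == "m2", ]
  expect_true(is.na(m2$alpha))     # stationary: exponent undefined
  expect_equal(m2$speed_nm_s, 0)
  ang <- cohort_angles(track_table(tt))
  expect_true(all(ang$track_id == "m1"))
})

test_that("confined cells backtrack more than freely diffusing cells", {
  conf <- simulate_tracks(track_sim_spec(60, 50, model = "confined_box",
                                         box_um = 10, step_um = 2,
                                         start = rep(5, 3), seed = 21))
  free <- simulate_tracks(track_sim_spec(60, 50, model = "fbm", hurst = 0.5,
                                         step_um = 2, seed = 22))
  back_frac <- function(tt) {
    a <- cohort_angles(tt)$angle_deg
    mean(a > 150)
  }
  expect_gt(back_frac(conf), back_frac(free))
})
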