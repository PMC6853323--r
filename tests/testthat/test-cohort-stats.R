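test_that("percentile thresholds use interpolated order statistics", {
  expect_equal(percentile_threshold(1:100, 0.75), 75.25)
  expect_equal(percentile_threshold(c(1, 2, 3, 4), 0.5), 2.5)
  expect_equal(percentile_threshold(rep(3.7, 10), 0.75), 3.7)
  expect_error(percentile_threshold(numeric(0)),
               class = "migr3d_degenerate_input")
  # positive rescaling scales the threshold by the same constant
  withr::with_seed(2, {
    v <- rexp(57)
    for (cc in c(0.2, 5)) {
      expect_equal(percentile_threshold(cc * v, 0.75),
                   cc * percentile_threshold(v, 0.75))
    }
  })
})

test_that("pore-size bins are zero-anchored, half-open and conserving", {
  rec <- data.frame(local_pore_size_um = 1:10,
                    speed_nm_s = c(5, 1, 6, 2, 7, 3, 8, 4, 9, 10))
  pred <- rec$speed_nm_s > median(rec$speed_nm_s)
  bf <- binned_fractions(rec, pred, 4)
  expect_equal(bf$n, c(3L, 4L, 3L))
  expect_equal(bf$bin_lo_um, c(0, 4, 8))
  expect_equal(bf$k, c(sum(pred[1:3]), sum(pred[4:7]), sum(pred[8:10])))
  expect_equal(sum(bf$k), sum(pred))
  expect_equal(sum(bf$n), nrow(rec))
  # bin edges are left-closed: a value exactly at an edge joins the
  # upper bin
  bf2 <- binned_fractions(data.frame(local_pore_size_um = c(4, 4.0001)),
                          c(TRUE, TRUE), 4)
  expect_equal(bf2$n, c(0L, 2L))
  expect_true(is.na(bf2$fraction[1]))  # empty bin: undefined, not zero
  expect_error(binned_fractions(data.frame(x = 1), TRUE, 4),
               class = "migr3d_validation_error")
  expect_error(binned_fractions(rec[0, ], logical(0), 4),
               class = "migr3d_validation_error")
})

test_that("the exact two-proportion test matches brute-force enumeration", {
  # all tables with n1, n2 <= 12
  for (n1 in c(3, 7, 12)) {
    for (n2 in c(4, 12)) {
      for (k1 in 0:n1) {
        for (k2 in 0:n2) {
          p <- binomial_fraction_test(k1, n1, k2, n2)$p_value
          expect_equal(p, min(oracle_fraction_test(k1, n1, k2, n2), 1),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # and agrees with the independent conditional-exact implementation in
  # base R
  for (tb in list(c(3, 9, 8, 10), c(10, 10, 0, 10), c(5, 10, 5, 10))) {
    p <- binomial_fraction_test(tb[1], tb[2], tb[3], tb[4])$p_value
    ref <- stats::fisher.test(matrix(c(tb[1], tb[2] - tb[1],
                                       tb[3], tb[4] - tb[3]), 2,
                                     byrow = TRUE))$p.value
    expect_equal(p, ref, tolerance = 1e-9)
  }
  expect_equal(binomial_fraction_test(5, 10, 5, 10)$p_value, 1)
  # complete separation at n = 10 + 10: enumerated two-sided tail
  expect_equal(binomial_fraction_test(10, 10, 0, 10)$p_value,
               2 / choose(20, 10), tolerance = 1e-9)
  # symmetry in the two groups
  expect_equal(binomial_fraction_test(3, 9, 7, 11)$p_value,
               binomial_fraction_test(7, 11, 3, 9)$p_value)
  expect_error(binomial_fraction_test(0, 0, 1, 2),
               class = "migr3d_degenerate_input")
  # one-sample binomial-vs-pooled reading stays available
  p1 <- binomial_fraction_test(9, 10, 2, 10,
                               method = "binomial_vs_pooled")$p_value
  expect_true(p1 > 0 && p1 < 1)
})

test_that("group tests route by Shapiro-Wilk normality gates", {
  withr::with_seed(8, {
    g_norm <- list(a = rnorm(200), b = rnorm(200, 0.1))
    g_heavy <- list(a = rlnorm(200, sdlog = 1.5), b = rlnorm(200, 0.5, 1.5))
  })
  t_res <- gated_group_test(g_norm)
  expect_equal(t_res$test, "two-sample t (Welch)")
  expect_true(all(t_res$normality_p > 0.05))
  mw <- gated_group_test(g_heavy)
  expect_equal(mw$test, "Mann-Whitney")
  kw <- gated_group_test(c(g_heavy, list(c = rnorm(50))))
  expect_equal(kw$test, "Kruskal-Wallis")
  expect_length(kw$routing, 4L)
  expect_error(gated_group_test(list(a = 1:2, b = 1:10)),
               class = "migr3d_length_error")
})

test_that("boxplot summaries follow the mean/quartile/whisker convention", {
  s <- boxplot_summary(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q25, 25.75)
  expect_equal(s$q75, 75.25)
  expect_equal(s$whisker_lo, 5.95)
  expect_equal(s$whisker_hi, 95.05)
  expect_equal(s$mean, 50.5)
  expect_setequal(s$outliers, c(1:5, 96:100))
  const <- boxplot_summary(rep(2, 10))
  expect_equal(const$median, const$whisker_lo)
  expect_length(const$outliers, 0L)
  one <- boxplot_summary(3)
  expect_equal(one$mean, 3)
  expect_error(boxplot_summary(numeric(0)),
               class = "migr3d_degenerate_input")
})

test_that("angle histograms are normalized and match 3D isotropy", {
  h <- angle_histogram(rep(180, 5), 20)
  expect_equal(h$fraction[nrow(h)], 1)
  expect_equal(sum(h$fraction), 1)
  expect_error(angle_histogram(numeric(0)), class = "migr3d_validation_error")
  expect_error(angle_histogram(c(10, 200)), class = "migr3d_validation_error")
  # isotropic 3D steps: fraction in [a, b] = (cos a - cos b) / 2
  withr::with_seed(12, {
    ang <- compute_turning_angles(random_walk_pos(20000))
    hh <- angle_histogram(ang, 30)
    lo <- hh$bin_lo_deg * pi / 180; hi <- hh$bin_hi_deg * pi / 180
    expect_frac <- (cos(lo) - cos(hi)) / 2
    n <- sum(hh$count)
    se <- sqrt(expect_frac * (1 - expect_frac) / n)
    expect_true(all(abs(hh$fraction - expect_frac) < 3 * se + 1e-12))
  })
})

test_that("cell records join features with local pore sizes", {
  vol <- simulate_network(network_sim_spec(c(20, 10, 10), 0.5,
                                           placement = "parallel_pairs",
                                           pair_spacing_um = 14,
                                           fiber_radius_um = 1))
  pm <- local_thickness(vol, "background")
  tt <- simulate_tracks(track_sim_spec(4, 10, model = "confined_box",
                                       box_um = 10, step_um = 0.3,
                                       start = c(5, 5, 5), seed = 3,
                                       phenotype = "A2"))
  feats <- track_features(tt)
  rec <- cell_records(feats, tt, pm)
  expect_true(all(abs(rec$local_pore_size_um - 14) <= 0.5 + 1e-9))
  expect_true(all(rec$phenotype == "A2"))
})
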