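test_that("barycenter is the unit-mass mean and translation-equivariant", {
  expect_equal(unname(barycenter(localization_table(3, 4))), c(3, 4))
  expect_equal(unname(barycenter(localization_table(c(0, 2), c(0, 2)))), c(1, 1))
  set.seed(1)
  tab <- localization_table(rnorm(50), rnorm(50))
  shifted <- localization_table(tab$x + 12.5, tab$y - 3.25)
  expect_equal(barycenter(shifted), barycenter(tab) + c(x = 12.5, y = -3.25))
  expect_error(barycenter(localization_table(numeric(0), numeric(0))), "empty")
})

test_that("radius of gyration matches hand values and the uniform-ball form", {
  expect_equal(radius_of_gyration(localization_table(5, 5)), 0)
  sq <- localization_table(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(radius_of_gyration(sq), sqrt(0.5), tolerance = 1e-12)
  set.seed(2)
  P <- runif_ball(50000, 180)
  tab <- localization_table(P[, 1], P[, 2], z = P[, 3])
  expect_equal(radius_of_gyration(tab, "3d"), 180 * sqrt(3 / 5), tolerance = 0.01)
})

test_that("focus assignment applies the strict half-major-axis rule with tie-breaks", {
  tadA <- cluster_metrics(localization_table(c(-100, 100, 0, 0), c(0, 0, -100, 100)))
  tadB <- cluster_metrics(localization_table(c(900, 1100, 1000, 1000), c(0, 0, -100, 100)))
  at_center <- cluster_metrics(localization_table(c(-1, 1), c(0, 0)))
  far <- cluster_metrics(localization_table(c(-1, 1) + 0.6 * tadA$major_axis, c(0, 0)))
  midway <- cluster_metrics(localization_table(c(499, 501), c(0, 0)))
  asg <- assign_foci(list(at_center, far, midway), list(tadA, tadB))
  expect_true(asg$assigned[1]); expect_equal(asg$tad[1], 1L)
  expect_false(asg$assigned[2])                       # 0.6 x major axis: excluded
  expect_equal(asg$tad[3], 1L)                        # equidistant: lower index
  expect_false(asg$assigned[3])
  none <- assign_foci(list(at_center), list())
  expect_false(any(none$assigned))
})

test_that("the two normalization conventions scale consistently and preserve order", {
  set.seed(3)
  tad <- simulate_tad(tad_spec(n_localizations = 3000), seed = 3)
  tcl <- cluster_metrics(tad$table)
  fs <- focus_spec(tad_spec(n_localizations = 10), n_foci = 50,
                   radial_fraction = "random", locs_per_focus = 40)
  foc <- simulate_foci(fs, seed = 4)
  vals <- t(sapply(1:50, function(i) {
    fc <- cluster_metrics(foc$table[foc$truth$label == i, , drop = FALSE])
    c(h = barycenter_distance(fc, tcl, "half_major_axis")$value,
      r = barycenter_distance(fc, tcl, "rg")$value)
  }))
  ratio <- (tcl$major_axis / 2) / tcl$rg
  expect_equal(vals[, "r"], vals[, "h"] * ratio, tolerance = 1e-10)
  expect_equal(cor(vals[, "r"], vals[, "h"], method = "spearman"), 1)
  pt <- cluster_metrics(localization_table(5, 5))
  expect_error(barycenter_distance(pt, pt), "degenerate")
})

test_that("analytic null values are correct and Monte Carlo confirms each", {
  expect_equal(null_distance("uniform_ball_projected", "mean")$value, 3 * pi / 16)
  expect_equal(null_distance("uniform_ball_3d", "mean")$value, 3 / 4)
  expect_equal(null_distance("uniform_disk", "mean")$value, 2 / 3)
  expect_equal(null_distance("uniform_disk", "median")$value, sqrt(0.5))
  expect_equal(null_distance("uniform_ball_3d", "median")$value, 0.5 ^ (1 / 3))
  for (g in c("uniform_ball_projected", "uniform_ball_3d", "uniform_disk")) {
    for (s in c("mean", "median")) {
      if (g == "uniform_ball_projected" && s == "median") next
      mc <- null_distance(g, s, method = "monte_carlo", n_draws = 2e5, seed = 17)
      an <- null_distance(g, s)
      expect_lt(abs(mc$value - an$value), 3 * mc$se)
    }
  }
  expect_error(null_distance("uniform_ball_projected", "median"), "monte_carlo")
  # rg normalizer rescales by the geometry's R/Rg
  expect_equal(null_distance("uniform_disk", "mean", normalizer = "rg")$value,
               (2 / 3) * sqrt(2))
})

test_that("RDD matches closed forms and grows with planted radial position", {
  tad <- cluster_metrics(localization_table(c(0, 0), c(-1, 1)))
  expect_equal(rdd(localization_table(c(0, 0), c(0, 0)), tad)$value, 0)
  set.seed(5)
  P <- runif_ball(50000)
  ball <- localization_table(P[, 1], P[, 2], z = P[, 3])
  tcl <- cluster_metrics(ball, dims = "3d")
  got <- rdd(ball, tcl, tendency = "median", normalizer = "rg", dims = "3d")
  expect_equal(got$value, 0.5 ^ (1 / 3) / sqrt(3 / 5), tolerance = 0.01)
  # monotone in the planted radial fraction, every seed
  for (seed in 1:5) {
    sp <- tad_spec(n_localizations = 1500)
    tadt <- simulate_tad(sp, seed = seed)
    tc <- cluster_metrics(tadt$table)
    vals <- sapply(c(0.2, 1.0), function(d) {
      foc <- simulate_foci(focus_spec(sp, n_foci = 7, radial_fraction = d),
                           seed = seed)
      rdd(foc$table, tc)$value
    })
    expect_lt(vals[1], vals[2])
  }
})

test_that("subsampling stability: exactness at fraction 1, variance ordering below", {
  tad <- simulate_tad(tad_spec(n_localizations = 2000), seed = 6)
  full <- subsample_robustness(tad$table, fractions = 1, reps = 5, seed = 1)
  expect_equal(full$rg_sd, 0)
  expect_equal(full$rg_mean, attr(full, "full_rg"))
  sds <- sapply(1:20, function(s) {
    out <- subsample_robustness(tad$table, fractions = c(0.5, 0.25),
                                reps = 10, seed = s)
    out$rg_sd
  })
  expect_gt(mean(sds[2, ]), mean(sds[1, ]))   # sparser subsample, larger spread
  expect_error(subsample_robustness(tad$table, fractions = 1e-4), "fewer than 2")
})

test_that("normalized statistics are invariant to translation, rotation and scale", {
  set.seed(7)
  sp <- tad_spec(n_localizations = 2000)
  tad <- simulate_tad(sp, seed = 7)
  foc <- simulate_foci(focus_spec(sp, n_foci = 1, radial_fraction = 0.6,
                                  locs_per_focus = 300), seed = 7)
  stat <- function(tt, ft) {
    tc <- cluster_metrics(tt); fc <- cluster_metrics(ft)
    c(bd = barycenter_distance(fc, tc)$value, rdd = rdd(ft, tc)$value)
  }
  base <- stat(tad$table, foc$table)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xf <- function(tab, s) {
    P <- s * cbind(tab$x, tab$y) %*% R
    localization_table(P[, 1] + 1e4, P[, 2] - 2e3)
  }
  moved <- stat(xf(tad$table, 3.5), xf(foc$table, 3.5))
  expect_equal(moved, base, tolerance = 1e-10)
})
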