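test_that("identical bead frames give an all-zero drift trace", {
  set.seed(2)
  img <- matrix(rpois(64 * 64, 5), 64, 64)
  img[20:24, 30:34] <- img[20:24, 30:34] + 500
  st <- image_stack(array(rep(img, 4), c(64, 64, 4)) |> aperm(c(3, 1, 2)),
                    pixel_size_nm = 160, frame_index = c(0L, 100L, 200L, 300L))
  tr <- estimate_drift(st, block_size = 100)
  expect_equal(max(abs(c(tr$dx, tr$dy))), 0)
})

test_that("a featureless bead block is refused", {
  st <- image_stack(array(3, c(3, 32, 32)), frame_index = c(0L, 50L, 100L))
  expect_error(estimate_drift(st, block_size = 50), "featureless")
})

test_that("injected linear drift is recovered within 0.1 px", {
  tr_true <- linear_drift(80, -40, 1000)          # 0.5 px, -0.25 px at 160 nm/px
  empty <- localization_table(numeric(0), numeric(0))
  mv <- simulate_movie(empty, drift = tr_true, n_frames = 1000,
                       bead_interval = 25, seed = 3)
  est <- estimate_drift(mv$beads, block_size = 50)
  fr <- seq(0, 999, by = 111)
  err <- drift_at(est, fr) - drift_at(tr_true, fr)
  expect_lt(max(abs(err)) / 160, 0.1)
})

test_that("drift subtraction is exact, order preserving, and restores Rg", {
  tad <- simulate_tad(tad_spec(n_localizations = 1500), seed = 6)
  tab <- tad$table
  zero <- drift_trace(c(0L, 1999L), c(0, 0), c(0, 0))
  expect_identical(apply_drift(tab, zero), tab)
  const <- drift_trace(c(0L, 1999L), c(10, 10), c(-5, -5))
  shifted <- apply_drift(tab, const)
  expect_equal(shifted$x, tab$x - 10)
  expect_equal(shifted$y, tab$y + 5)
  expect_identical(shifted[, c("frame", "channel", "photons")],
                   tab[, c("frame", "channel", "photons")])
  # drift + bead-based correction preserves the cluster's Rg within 2%
  rg0 <- radius_of_gyration(tab)
  tr <- linear_drift(160, 120, 2000)
  dd <- drift_at(tr, tab$frame)
  tab$x <- tab$x + dd[, "dx"]; tab$y <- tab$y + dd[, "dy"]
  mv <- simulate_movie(tab[0, ], drift = tr, n_frames = 2000,
                       bead_interval = 50, seed = 8)
  corrected <- apply_drift(tab, estimate_drift(mv$beads, block_size = 100))
  expect_equal(radius_of_gyration(corrected), rg0, tolerance = 0.02)
  expect_error(apply_drift(tab, drift_trace(c(0L, 500L), c(0, 1), c(0, 1))),
               "outside")
})

test_that("channel registration recovers translations and affine maps", {
  set.seed(10)
  p1 <- cbind(runif(12, 0, 5000), runif(12, 0, 5000))
  ident <- register_channels(p1, p1)
  expect_equal(unname(ident$params), c(0, 0))
  expect_equal(ident$residual_nm, 0)
  tr <- register_channels(p1, sweep(p1, 2, c(30, -12), `-`))
  expect_equal(unname(tr$params), c(30, -12))
  # known affine + 5 nm noise: parameters recovered, residual at noise level
  A <- matrix(c(1.002, 0.003, -0.001, 0.998), 2, 2)
  b <- c(25, -40)
  p2 <- t(solve(A) %*% (t(p1) - b + matrix(rnorm(24, 0, 5), 2)))
  aff <- register_channels(p1, p2, mode = "affine")
  expect_equal(aff$params[, 1:2], A, tolerance = 0.02)
  expect_lt(abs(aff$residual_nm - 5), 4)
  mapped <- apply_transform(aff, p2)
  expect_lt(sqrt(mean((mapped - p1) ^ 2)), 8)
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(register_channels(coll, coll, mode = "affine"), "collinear")
})
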