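test_that("spot detection finds isolated maxima and suppresses close pairs", {
  expect_equal(nrow(detect_spots(matrix(0, 16, 16), threshold = 1)), 0L)
  fr <- matrix(0, 16, 16); fr[8, 9] <- 100
  got <- detect_spots(fr, threshold = 50)
  expect_equal(got[, c("row", "col")], data.frame(row = 8L, col = 9L))
  # two noiseless Gaussians 10 px apart survive suppression at min_separation 3
  fr2 <- stormtad:::.gauss_patch(21, 21, x0 = 5.5, y0 = 10.5, 1.3, 1.3, 4000, 0) +
    stormtad:::.gauss_patch(21, 21, x0 = 15.5, y0 = 10.5, 1.3, 1.3, 4000, 0)
  got2 <- detect_spots(fr2, threshold = 100, min_separation = 3)
  expect_equal(nrow(got2), 2L)
  expect_setequal(got2$col, c(6L, 16L))
})

test_that("noiseless elliptical Gaussian fits are exact to optimizer tolerance", {
  patch <- stormtad:::.gauss_patch(11, 11, x0 = 5.3, y0 = 4.7,
                                   sx = 1.2, sy = 1.5, A = 5000, offset = 10)
  f <- fit_gaussian(patch)
  expect_true(f$ok)
  expect_lt(abs(f$x - 5.3), 1e-6)
  expect_lt(abs(f$y - 4.7), 1e-6)
  expect_lt(abs(f$width_x - 1.2) / 1.2, 1e-6)
  expect_lt(abs(f$width_y - 1.5) / 1.5, 1e-6)
  expect_lt(abs(f$amplitude - 5000) / 5000, 1e-6)
  expect_false(fit_gaussian(matrix(7, 9, 9))$ok)   # flat patch flagged
})

test_that("Poisson-noise localization error matches the LSQ error propagation", {
  # first-order sandwich covariance of the unweighted least-squares
  # estimator under Poisson noise -- the independent prediction; the
  # idealized sigma/sqrt(N) bound is a scaling check (plain LSQ with a
  # fitted offset is not an efficient estimator, so some excess over the
  # ideal bound is expected)
  p0 <- c(5.3, 4.7, 1.2, 1.5, 5000, 0)
  mu_fun <- function(p) as.vector(stormtad:::.gauss_patch(11, 11, p[1], p[2],
                                                          p[3], p[4], p[5], p[6]))
  J <- sapply(seq_along(p0), function(k) {
    h <- max(1e-6, 1e-6 * abs(p0[k]))
    pp <- p0; pp[k] <- pp[k] + h
    pm <- p0; pm[k] <- pm[k] - h
    (mu_fun(pp) - mu_fun(pm)) / (2 * h)
  })
  mu <- mu_fun(p0)
  Ai <- solve(crossprod(J))
  S <- Ai %*% t(J) %*% (J * mu) %*% Ai
  set.seed(99)
  reps <- 300
  err <- matrix(0, reps, 2)
  for (k in seq_len(reps)) {
    f <- fit_gaussian(matrix(rpois(121, mu), 11, 11))
    err[k, ] <- c(f$x - p0[1], f$y - p0[2])
  }
  rms <- sqrt(colMeans(err ^ 2))
  expect_lt(abs(rms[1] - sqrt(S[1, 1])) / sqrt(S[1, 1]), 0.15)
  expect_lt(abs(rms[2] - sqrt(S[2, 2])) / sqrt(S[2, 2]), 0.15)
  expect_lt(rms[1], 1.6 * p0[3] / sqrt(p0[5]))     # tracks shot-noise scaling
  expect_lt(rms[2], 1.6 * p0[4] / sqrt(p0[5]))
})

test_that("calibration fitting round-trips the defocus widths and validates shape", {
  wt <- astig_width_table()
  cal <- build_calibration(wt)
  pred <- predict_widths(cal, wt$z)
  expect_lt(sqrt(mean((pred$wx - wt$wx) ^ 2 + (pred$wy - wt$wy) ^ 2)), 1)
  # swapping wx and wy mirrors the calibration: looked-up z flips sign
  swapped <- build_calibration(data.frame(z = wt$z, wx = wt$wy, wy = wt$wx))
  w300 <- stormtad:::.astig_widths(300)
  expect_equal(z_lookup(w300$wx, w300$wy, cal), 300, tolerance = 1e-2)
  expect_equal(z_lookup(w300$wx, w300$wy, swapped), -300, tolerance = 1e-2)
  flat <- data.frame(z = wt$z, wx = 200, wy = 200)
  expect_error(build_calibration(flat), "astigmatic")
  expect_error(build_calibration(wt[1:5, ]), "at least 10")
})

test_that("z lookup is exact at the focal plane and rejects off-curve widths", {
  cal <- build_calibration(astig_width_table())
  w0 <- stormtad:::.astig_widths(0)
  expect_equal(z_lookup(w0$wx, w0$wy, cal), 0, tolerance = 1e-6)
  # widths far from anything on the curve are rejected as NA
  expect_true(is.na(z_lookup(600, 600, cal, cutoff = 0.1)))
  expect_error(z_lookup(-1, 150, cal), "positive")
})

test_that("simulated movies localize back to the planted emitters", {
  cal <- build_calibration(astig_width_table())
  set.seed(5)
  em <- localization_table(runif(60, 1500, 8500), runif(60, 1500, 8500),
                           z = runif(60, -400, 400), frame = 0:59,
                           photons = 5000)
  w <- stormtad:::.astig_widths(em$z)
  em$width_x <- w$wx; em$width_y <- w$wy
  mv <- simulate_movie(em, calibration = cal, photon_mean = 5000,
                       background = 2, n_frames = 60, seed = 4)
  # determinism of the renderer
  mv2 <- simulate_movie(em, calibration = cal, photon_mean = 5000,
                        background = 2, n_frames = 60, seed = 4)
  expect_identical(mv$movie$frames, mv2$movie$frames)
  loc <- localize_stack(mv$movie, threshold = 30, calibration = cal)
  m <- merge(as.data.frame(em), as.data.frame(loc), by = "frame")
  lateral <- sqrt((m$x.x - m$x.y) ^ 2 + (m$y.x - m$y.y) ^ 2)
  axial <- abs(m$z.x - m$z.y)
  expect_gte(mean(lateral < 20), 0.95)
  expect_gte(mean(axial < 50), 0.95)
})

test_that("a single emitter at a pixel center peaks at that pixel", {
  tab <- localization_table(15.5 * 160, 10.5 * 160, frame = 0, photons = 1e4)
  mv <- simulate_movie(tab, background = 0, n_frames = 1,
                       camera = list(nx = 32, ny = 32, pixel_size_nm = 160),
                       seed = 1)
  fr <- mv$movie$frames[1, , ]
  pk <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(11L, 16L))
})

test_that("emitters outside the calibrated range are refused by name", {
  cal <- build_calibration(astig_width_table(z = seq(-300, 300, 50)))
  em <- localization_table(c(1000, 2000), c(1000, 2000), z = c(0, 500),
                           frame = 0:1)
  expect_error(simulate_movie(em, calibration = cal, n_frames = 2, seed = 1),
               "row 2")
})
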