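test_that("two-radius DBSCAN handles the elementary contract cases", {
  tab <- localization_table(c(0, 0, 0), c(0, 1, 2))
  got <- dbscan_clusters(tab, dbscan_params(r = 1.5, n_min = 1, r_ref = 1.5))
  expect_equal(got$labels, c(1L, 1L, 1L))
  # isolated point below the core threshold is noise
  lone <- dbscan_clusters(localization_table(0, 0), dbscan_params(1, 2))
  expect_equal(lone$labels, 0L)
  expect_length(lone$clusters, 0)
  # empty input is an empty result, not an error
  empty <- dbscan_clusters(localization_table(numeric(0), numeric(0)),
                           dbscan_params(1, 1))
  expect_length(empty$labels, 0)
})

test_that("two planted blobs far apart are recovered exactly", {
  set.seed(21)
  a <- runif_disk(50, 20)
  b <- sweep(runif_disk(50, 20), 2, c(500, 0), `+`)
  tab <- localization_table(c(a[, 1], b[, 1]), c(a[, 2], b[, 2]))
  got <- dbscan_clusters(tab, dbscan_params(r = 15, n_min = 3, r_ref = 15))
  expect_length(got$clusters, 2)
  expect_setequal(got$clusters[[1]], 1:50)
  expect_setequal(got$clusters[[2]], 51:100)
})

test_that("DBSCAN matches the brute-force reference on random instances", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(20:120, 1)
    P <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    r <- runif(1, 5, 20); n_min <- sample(2:5, 1); r_ref <- runif(1, 5, 25)
    tab <- localization_table(P[, 1], P[, 2])
    got <- dbscan_clusters(tab, dbscan_params(r, n_min, r_ref))
    expect_identical(canonical_partition(got$labels),
                     canonical_partition(brute_dbscan(P, r, n_min, r_ref)),
                     info = paste("seed", seed))
  }
})

test_that("DBSCAN is invariant to row permutation up to relabeling", {
  set.seed(33)
  P <- rbind(runif_disk(60, 30),
             sweep(runif_disk(60, 30), 2, c(120, 40), `+`),
             cbind(runif(30, -200, 300), runif(30, -200, 300)))
  tab <- localization_table(P[, 1], P[, 2])
  par <- dbscan_params(r = 12, n_min = 3)
  base <- dbscan_clusters(tab, par)
  perm <- sample(nrow(P))
  shuf <- dbscan_clusters(localization_table(P[perm, 1], P[perm, 2]), par)
  got <- canonical_partition(shuf$labels)
  remapped <- lapply(got, function(idx) sort(perm[idx]))
  remapped <- remapped[order(vapply(remapped, min, integer(1)))]
  expect_identical(remapped, canonical_partition(base$labels))
})

test_that("auto thresholds follow their documented density heuristic", {
  set.seed(44)
  tab <- localization_table(runif(2000, 0, 1000), runif(2000, 0, 1000))
  par <- suppressMessages(auto_thresholds(tab))
  P <- cbind(tab$x, tab$y)
  rho <- 2000 / stormtad:::.hull_measure(P)
  expect_lte(abs(par$n_min - max(4, round(rho * pi * par$r ^ 2))), 1)
  # scale equivariance: x2 coordinates double the radii, n_min unchanged
  tab2 <- localization_table(tab$x * 2, tab$y * 2)
  par2 <- suppressMessages(auto_thresholds(tab2))
  expect_equal(par2$r, 2 * par$r, tolerance = 1e-10)
  expect_equal(par2$r_ref, 2 * par$r_ref, tolerance = 1e-10)
  expect_equal(par2$n_min, par$n_min)
  expect_error(suppressMessages(
    auto_thresholds(localization_table(1:5, 1:5))), "at least 10")
})

test_that("a regular grid yields no Voronoi clusters at density factor 3", {
  g <- expand.grid(x = 1:20, y = 1:20)
  got <- voronoi_density_segment(localization_table(g$x, g$y),
                                 density_factor = 3, min_detections = 1)
  expect_length(got$clusters, 0)
})

test_that("a planted dense blob is recovered against sparse background", {
  set.seed(55)
  blob <- matrix(rnorm(200, sd = 10), ncol = 2)
  bgn <- cbind(runif(100, -500, 500), runif(100, -500, 500))
  tab <- localization_table(c(blob[, 1], bgn[, 1]), c(blob[, 2], bgn[, 2]))
  got <- voronoi_density_segment(tab, density_factor = 3)
  expect_length(got$clusters, 1)
  expect_gte(sum(got$clusters[[1]] <= 100), 90)
})

test_that("Voronoi selection is monotone in the density factor and disjoint", {
  set.seed(66)
  P <- rbind(matrix(rnorm(160, sd = 15), ncol = 2),
             cbind(runif(120, -400, 400), runif(120, -400, 400)))
  tab <- localization_table(P[, 1], P[, 2])
  segs <- lapply(c(2, 3, 5, 10), function(df)
    voronoi_density_segment(tab, density_factor = df, min_detections = 1))
  sel <- lapply(segs, function(s) which(s$labels > 0))
  for (k in 2:4) expect_true(all(sel[[k]] %in% sel[[k - 1]]))
  for (s in segs) {
    members <- unlist(s$clusters)
    expect_lte(length(members), nrow(P))
    expect_false(any(duplicated(members)))
  }
  expect_error(voronoi_density_segment(localization_table(1:9, 2 * (1:9))),
               "collinear")
  expect_error(voronoi_density_segment(localization_table(1, 1)), "at least 4")
})

test_that("cluster metrics match hand computations and closed forms", {
  sq <- localization_table(c(0, 1, 1, 0), c(0, 0, 1, 1))
  m <- cluster_metrics(sq)
  expect_equal(unname(m$barycenter), c(0.5, 0.5))
  expect_equal(m$rg, sqrt(0.5), tolerance = 1e-12)
  expect_equal(m$diameter, sqrt(2), tolerance = 1e-12)
  two <- cluster_metrics(localization_table(c(0, 2), c(0, 0)))
  expect_equal(unname(two$barycenter), c(1, 0))
  expect_equal(two$rg, 1, tolerance = 1e-12)
  expect_equal(two$diameter, 2)
  set.seed(77)
  P <- runif_disk(10000, 150)
  big <- cluster_metrics(localization_table(P[, 1], P[, 2]))
  expect_equal(big$rg, 150 / sqrt(2), tolerance = 0.01)
  expect_equal(big$diameter, 300, tolerance = 0.02)
  expect_equal(big$major_axis, 4 * 150 / 2, tolerance = 0.03)  # 4 sigma_PC1
  # Rg^2 is exactly the mean squared distance to the barycenter
  d2 <- rowSums(sweep(P, 2, colMeans(P)) ^ 2)
  expect_equal(big$rg ^ 2, mean(d2), tolerance = 1e-12)
  single <- cluster_metrics(localization_table(5, 7))
  expect_equal(single$major_axis, 0)
  expect_equal(single$diameter, 0)
  expect_true(is.na(single$density))
})
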