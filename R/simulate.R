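#' Specify a synthetic TAD
#'
#' A TAD is emulated as a compact localization cloud. The default geometry is
#' a uniform disk: the principal statistics of the study are computed on
#' 2D-projected localizations (x/y exports), and for a uniform disk the half
#' major axis (two principal-component sigmas) equals the disk radius in
#' expectation, so planted radial positions are recovered on the same scale
#' they were planted. 3D shapes (uniform ball, ellipsoid, isotropic
#' Gaussian) serve the astigmatism/3D paths.
#'
#' @param center TAD center in nm, length 2 or 3.
#' @param shape one of `"disk_uniform"`, `"sphere_uniform"`,
#'   `"ellipsoid_uniform"`, `"gaussian"`. For `"gaussian"` `radius_nm` is the
#'   isotropic sigma; for `"ellipsoid_uniform"` it may be a length-3 vector
#'   of semi-axes.
#' @param radius_nm nominal radius (nm). A disk of radius R has a measured
#'   2D radius of gyration R/sqrt(2); a ball, R*sqrt(3/5) in 3D.
#' @param n_localizations number of localizations to draw.
#' @param precision_nm localization precision as (lateral, axial) Gaussian
#'   sigmas in nm; the study regime is about (20, 50).
#' @return a list of class `"tad_spec"`.
#' @export
tad_spec <- function(center = c(0, 0, 0), shape = "disk_uniform",
                     radius_nm = 283, n_localizations = 2500,
                     precision_nm = c(20, 50)) {
  shape <- match.arg(shape, c("disk_uniform", "sphere_uniform",
                              "ellipsoid_uniform", "gaussian"))
  if (length(center) == 2) center <- c(center, 0)
  stopifnot(all(radius_nm > 0), n_localizations >= 1, all(precision_nm >= 0))
  structure(list(center = as.numeric(center), shape = shape,
                 radius_nm = as.numeric(radius_nm),
                 n_localizations = as.integer(n_localizations),
                 precision_nm = as.numeric(rep_len(precision_nm, 2))),
            class = "tad_spec")
}

#' Specify replication foci inside a TAD
#'
#' @param parent the [tad_spec()] the foci live in.
#' @param n_foci number of foci (the study's domains carry ~7 initiation
#'   sites on average).
#' @param radial_fraction either a number (or per-focus vector) d in
#'   `[0, 1]`: each focus center is placed at distance `d * radius_nm` from
#'   the TAD center in a random direction — or the string `"random"`, which
#'   places centers uniformly in the TAD volume (the random-placement null).
#' @param focus_diameter_nm focus size (~30 nm in the study).
#' @param locs_per_focus localizations drawn per focus.
#' @return a list of class `"focus_spec"`.
#' @export
focus_spec <- function(parent, n_foci = 7, radial_fraction = "random",
                       focus_diameter_nm = 30, locs_per_focus = 200) {
  stopifnot(inherits(parent, "tad_spec"), n_foci >= 0, focus_diameter_nm > 0)
  if (!identical(radial_fraction, "random")) {
    radial_fraction <- as.numeric(radial_fraction)
    stopifnot(all(radial_fraction >= 0), all(radial_fraction <= 1.2))
  }
  structure(list(parent = parent, n_foci = as.integer(n_foci),
                 radial_fraction = radial_fraction,
                 focus_diameter_nm = as.numeric(focus_diameter_nm),
                 locs_per_focus = as.integer(locs_per_focus)),
            class = "focus_spec")
}

# n x 3 matrix of points from the unit-scale shape, scaled by R
.sample_shape <- function(n, shape, R) {
  switch(shape,
    disk_uniform = {
      r <- sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
      cbind(R[1] * r * cos(a), R[1] * r * sin(a), 0)
    },
    sphere_uniform = {
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u ^ 2))
      r <- runif(n) ^ (1 / 3)
      u * r * R[1]
    },
    ellipsoid_uniform = {
      ax <- rep_len(R, 3)
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u ^ 2))
      p <- u * runif(n) ^ (1 / 3)
      sweep(p, 2, ax, `*`)
    },
    gaussian = matrix(rnorm(3 * n, sd = R[1]), ncol = 3),
    stop("unknown shape: ", shape)
  )
}

.shape_is_2d <- function(shape) shape == "disk_uniform"

# random unit direction matched to the shape's dimensionality
.sample_direction <- function(n, shape) {
  if (.shape_is_2d(shape)) {
    a <- runif(n, 0, 2 * pi)
    cbind(cos(a), sin(a), 0)
  } else {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u / sqrt(rowSums(u ^ 2))
  }
}

.finish_table <- function(pos, spec, channel, n_frames, truth_label) {
  n <- nrow(pos)
  prec <- spec$precision_nm
  pos[, 1] <- pos[, 1] + rnorm(n, sd = prec[1])
  pos[, 2] <- pos[, 2] + rnorm(n, sd = prec[1])
  is2d <- .shape_is_2d(spec$shape)
  if (!is2d) pos[, 3] <- pos[, 3] + rnorm(n, sd = prec[2])
  frame <- sort(sample.int(n_frames, n, replace = TRUE) - 1L)
  photons <- rgamma(n, shape = 4, scale = 1250)
  if (is2d) {
    localization_table(pos[, 1], pos[, 2], frame = frame, channel = channel,
                       photons = photons)
  } else {
    w <- .astig_widths(pmin(pmax(pos[, 3] - spec$center[3], -600), 600))
    localization_table(pos[, 1], pos[, 2], z = pos[, 3], frame = frame,
                       channel = channel, photons = photons,
                       width_x = w$wx, width_y = w$wy)
  }
}

#' Simulate a TAD localization cloud
#'
#' Draws `n_localizations` points from the spec's shape, jitters each by the
#' localization precision, and attaches frames, photon counts and (for 3D
#' shapes) astigmatic PSF widths. Deterministic for a fixed seed.
#'
#' @param spec a [tad_spec()].
#' @param seed integer seed.
#' @param channel channel label for the table.
#' @param n_frames number of acquisition frames localizations spread over.
#' @return list with elements `table` (a [localization_table()]) and `truth`
#'   (center, radius, shape, per-row cluster label).
#' @export
simulate_tad <- function(spec, seed = 1L, channel = "647", n_frames = 2000L) {
  stopifnot(inherits(spec, "tad_spec"))
  if (spec$n_localizations < 1) stop("n_localizations must be >= 1")
  set.seed(seed)
  pos <- .sample_shape(spec$n_localizations, spec$shape, spec$radius_nm)
  pos <- sweep(pos, 2, spec$center, `+`)
  tab <- .finish_table(pos, spec, channel, n_frames)
  truth <- list(center = spec$center, radius_nm = spec$radius_nm,
                shape = spec$shape, label = rep("tad", nrow(tab)),
                true_z = pos[, 3], seed = seed)
  list(table = tab, truth = truth)
}

#' Simulate replication foci within a TAD
#'
#' Focus centers are placed at the requested radial fraction of the TAD
#' radius (random direction matched to the TAD's dimensionality), or
#' uniformly in the TAD volume when `radial_fraction = "random"`.
#' Localizations are then drawn uniformly within each focus sphere/disk and
#' jittered by the localization precision.
#'
#' @param spec a [focus_spec()].
#' @param seed integer seed.
#' @param channel channel label (default `"561"`, the second color).
#' @param n_frames acquisition frames to spread localizations over.
#' @return list with `table`, and `truth` holding per-focus true centers and
#'   radial fractions plus per-row focus labels.
#' @export
simulate_foci <- function(spec, seed = 1L, channel = "561", n_frames = 2000L) {
  stopifnot(inherits(spec, "focus_spec"))
  if (spec$locs_per_focus < 1) stop("locs_per_focus must be >= 1")
  parent <- spec$parent
  set.seed(seed + 1L)
  nf <- spec$n_foci
  if (identical(spec$radial_fraction, "random")) {
    centers <- .sample_shape(nf, parent$shape, parent$radius_nm)
    d_true <- sqrt(rowSums(centers ^ 2)) / parent$radius_nm[1]
  } else {
    d_true <- rep_len(spec$radial_fraction, nf)
    centers <- .sample_direction(nf, parent$shape) * (d_true * parent$radius_nm[1])
  }
  centers <- sweep(centers, 2, parent$center, `+`)
  fshape <- if (.shape_is_2d(parent$shape)) "disk_uniform" else "sphere_uniform"
  pos <- NULL; labels <- integer(0)
  for (i in seq_len(nf)) {
    p <- .sample_shape(spec$locs_per_focus, fshape, spec$focus_diameter_nm / 2)
    p <- sweep(p, 2, centers[i, ], `+`)
    pos <- rbind(pos, p)
    labels <- c(labels, rep.int(i, spec$locs_per_focus))
  }
  if (is.null(pos)) pos <- matrix(numeric(0), ncol = 3)
  tab <- .finish_table(pos, parent, channel, n_frames)
  truth <- list(centers = centers, radial_fraction = d_true,
                label = labels, true_z = pos[, 3], seed = seed)
  list(table = tab, truth = truth)
}

#' Simulate one dual-color cell
#'
#' Builds the study's standard scene: one TAD cloud in the reference channel
#' and its replication foci in the second channel, each with sparse uniform
#' background localizations so density-based segmentation has a noise floor
#' to beat. Presets mirror the study's conditions: `"g1_uniform"` (foci
#' placed uniformly at random in the TAD — the random null), `"g1s_peripheral"`
#' (foci at the TAD periphery, radial fraction 1) and `"interior"` (radial
#' fraction 0.2).
#'
#' @param preset `"g1_uniform"`, `"g1s_peripheral"` or `"interior"`.
#' @param seed integer seed.
#' @param sim list of generator settings (see [analysis_config()]); absent
#'   entries take the package defaults.
#' @return list with `table` (both channels, row-bound), `truth` (TAD +
#'   focus ground truth and channel labels), and `channels` naming the TAD
#'   and focus channels.
#' @export
simulate_cell <- function(preset = c("g1_uniform", "g1s_peripheral", "interior"),
                          seed = 1L, sim = list()) {
  preset <- match.arg(preset)
  sim <- modifyList(default_config()$simulate, sim)
  d <- switch(preset, g1_uniform = "random", g1s_peripheral = 1.0, interior = 0.2)
  ts <- tad_spec(center = c(0, 0, 0), shape = sim$shape %||% "disk_uniform",
                 radius_nm = sim$tad_radius_nm,
                 n_localizations = sim$n_tad_localizations,
                 precision_nm = sim$precision_nm)
  fs <- focus_spec(ts, n_foci = sim$n_foci, radial_fraction = d,
                   focus_diameter_nm = sim$focus_diameter_nm,
                   locs_per_focus = sim$locs_per_focus)
  tad <- simulate_tad(ts, seed = seed, channel = "647")
  foc <- simulate_foci(fs, seed = seed, channel = "561")
  set.seed(seed + 2L)
  half <- 2.5 * ts$radius_nm[1]
  nbg <- sim$background_per_channel
  bg <- function(channel) {
    localization_table(runif(nbg, -half, half), runif(nbg, -half, half),
                       frame = sort(sample.int(2000L, nbg, replace = TRUE) - 1L),
                       channel = channel, photons = rgamma(nbg, 4, scale = 1250))
  }
  tab <- .rbind_loc(tad$table, bg("647"), foc$table, bg("561"))
  list(table = tab,
       truth = list(tad = tad$truth, foci = foc$truth, preset = preset,
                    seed = seed,
                    label = c(rep("tad", nrow(tad$table)), rep("bg", nbg),
                              paste0("focus", foc$truth$label), rep("bg", nbg))),
       channels = c(tad = "647", focus = "561"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rbind_loc <- function(...) {
  tabs <- list(...)
  cols <- Reduce(intersect, lapply(tabs, names))
  out <- do.call(rbind, lapply(tabs, function(t) as.data.frame(t)[, cols, drop = FALSE]))
  rownames(out) <- NULL
  validate_localizations(out)
}
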