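#' Astigmatic defocus model and z calibration
#'
#' With a cylindrical lens in the detection path the PSF is elliptical away
#' from focus: the x and y Gaussian widths follow defocus curves whose minima
#' sit on opposite sides of the focal plane, and the pair (wx, wy) encodes z.
#' `astig_width_table()` generates a sampled calibration table from the
#' standard defocus model `w(z) = w0 * sqrt(1 + ((z -/+ gamma)/depth)^2)`,
#' the same model the synthetic movie renderer uses, so calibration and
#' rendering are mutually consistent.
#'
#' @param z stage z positions in nm.
#' @param w0 in-focus Gaussian width in nm.
#' @param gamma astigmatic focal offset in nm (wx focuses at +gamma, wy at
#'   -gamma; the curves cross at z = 0).
#' @param depth defocus depth scale in nm.
#' @return data frame with columns `z`, `wx`, `wy` (nm).
#' @export
astig_width_table <- function(z = seq(-600, 600, by = 50), w0 = 150,
                              gamma = 200, depth = 400) {
  w <- .astig_widths(z, w0, gamma, depth)
  data.frame(z = z, wx = w$wx, wy = w$wy)
}

.astig_widths <- function(z, w0 = 150, gamma = 200, depth = 400) {
  list(wx = w0 * sqrt(1 + ((z - gamma) / depth) ^ 2),
       wy = w0 * sqrt(1 + ((z + gamma) / depth) ^ 2))
}

#' Fit a z calibration curve from measured widths
#'
#' Fits polynomial curves wx(z), wy(z) (degree 4 by default) to a width
#' table measured by scanning fluorophores through z, and validates the two
#' invariants a usable astigmatism calibration must satisfy: the curves
#' cross at exactly one focal point inside the range, and each curve is
#' strictly monotone on either side of its minimum.
#'
#' @param width_table data frame with columns `z`, `wx`, `wy` in nm, at
#'   least 10 distinct z planes.
#' @param degree polynomial degree (default 6; a quartic cannot follow the
#'   square-root defocus form to nanometre accuracy over a +/-600 nm range).
#' @return object of class `"calibration_curve"` with the coefficients and
#'   valid z range.
#' @export
build_calibration <- function(width_table, degree = 6) {
  stopifnot(all(c("z", "wx", "wy") %in% names(width_table)))
  if (length(unique(width_table$z)) < 10)
    stop("need at least 10 z planes to build a calibration curve")
  fx <- lm(wx ~ poly(z, degree, raw = TRUE), data = width_table)
  fy <- lm(wy ~ poly(z, degree, raw = TRUE), data = width_table)
  rng <- range(width_table$z)
  zz <- seq(rng[1], rng[2], length.out = 1201)
  wxz <- .poly_eval(coef(fx), zz); wyz <- .poly_eval(coef(fy), zz)
  for (w in list(wxz, wyz)) {
    sgn <- sign(diff(w))
    flips <- sum(diff(sgn[sgn != 0]) != 0)
    if (flips != 1 || all(sgn >= 0) || all(sgn <= 0))
      stop("calibration widths are not astigmatic: each width must fall to a ",
           "single minimum and rise again across the z range")
  }
  cr <- sign(wxz - wyz)
  if (sum(diff(cr[cr != 0]) != 0) != 1)
    stop("calibration curves must cross at exactly one focal point in range")
  structure(list(coef_x = unname(coef(fx)), coef_y = unname(coef(fy)),
                 range = rng, degree = degree,
                 rms_residual = sqrt(mean(c(residuals(fx), residuals(fy)) ^ 2))),
            class = "calibration_curve")
}

.poly_eval <- function(coefs, z) {
  out <- numeric(length(z))
  for (k in seq_along(coefs)) out <- out + coefs[k] * z ^ (k - 1)
  out
}

#' Predict calibration widths at given z
#' @param calibration a [build_calibration()] result.
#' @param z z positions (nm) inside the calibrated range.
#' @return data frame with `z`, `wx`, `wy`.
#' @export
predict_widths <- function(calibration, z) {
  stopifnot(inherits(calibration, "calibration_curve"))
  if (any(z < calibration$range[1] | z > calibration$range[2]))
    stop("z outside calibrated range [", calibration$range[1], ", ",
         calibration$range[2], "] nm")
  data.frame(z = z, wx = .poly_eval(calibration$coef_x, z),
             wy = .poly_eval(calibration$coef_y, z))
}

#' Look up z from fitted PSF widths
#'
#' For each detection, finds the z minimizing the root-width distance
#' `D(z) = (sqrt(wx) - sqrt(wx(z)))^2 + (sqrt(wy) - sqrt(wy(z)))^2`
#' over the calibrated range (coarse grid then local refinement).
#' Detections whose minimal D exceeds `cutoff` are rejected (`NA`): their
#' width pair is not explained by any point on the calibration.
#'
#' @param width_x,width_y fitted widths in nm (vectors).
#' @param calibration a `"calibration_curve"`.
#' @param cutoff rejection threshold on D, in nm (root-width scale);
#'   default 0.1.
#' @param grid_nm coarse-grid step in nm.
#' @return numeric vector of z (nm), `NA` where rejected.
#' @export
z_lookup <- function(width_x, width_y, calibration, cutoff = 0.1, grid_nm = 2) {
  stopifnot(inherits(calibration, "calibration_curve"))
  if (any(width_x <= 0) || any(width_y <= 0)) stop("widths must be positive")
  rng <- calibration$range
  zz <- seq(rng[1], rng[2], by = grid_nm)
  sx <- sqrt(.poly_eval(calibration$coef_x, zz))
  sy <- sqrt(.poly_eval(calibration$coef_y, zz))
  out <- numeric(length(width_x))
  for (i in seq_along(width_x)) {
    D <- (sqrt(width_x[i]) - sx) ^ 2 + (sqrt(width_y[i]) - sy) ^ 2
    k <- which.min(D)
    lo <- zz[max(1, k - 1)]; hi <- zz[min(length(zz), k + 1)]
    f <- function(z) {
      w <- c(.poly_eval(calibration$coef_x, z), .poly_eval(calibration$coef_y, z))
      (sqrt(width_x[i]) - sqrt(w[1])) ^ 2 + (sqrt(width_y[i]) - sqrt(w[2])) ^ 2
    }
    op <- optimize(f, c(lo, hi))
    out[i] <- if (op$objective <= cutoff) op$minimum else NA_real_
  }
  out
}
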