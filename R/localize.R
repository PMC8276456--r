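#' Detect candidate spots in a camera frame
#'
#' Local maxima above an intensity threshold, with non-maximum suppression:
#' candidates are visited brightest-first and any candidate within
#' `min_separation` pixels of an already accepted one is dropped.
#'
#' @param frame 2D intensity matrix (rows = y, cols = x).
#' @param threshold minimum peak intensity in counts (must be > 0).
#' @param min_separation suppression radius in pixels.
#' @return data frame with 1-based `row`, `col` and `value` per candidate
#'   (zero rows when nothing exceeds the threshold).
#' @export
detect_spots <- function(frame, threshold, min_separation = 3) {
  stopifnot(is.matrix(frame), threshold > 0)
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 3 || nc < 3) return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  core <- frame[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (core >= frame[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     value = core[idx])
  cand <- cand[order(-cand$value), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i]) ^ 2 + (cand$col[keep] - cand$col[i]) ^ 2
    if (all(d2 >= min_separation ^ 2)) keep[i] <- TRUE
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

# pixel-integrated elliptical Gaussian: expected counts in pixel (i, j)
# (1-based; pixel j spans [j-1, j) in continuous pixel coordinates) for a
# total of A photons centered at (x0, y0) px with sigmas (sx, sy) px.
.gauss_patch <- function(nr, nc, x0, y0, sx, sy, A, offset) {
  gx <- pnorm((seq_len(nc) - x0) / sx) - pnorm((seq_len(nc) - 1 - x0) / sx)
  gy <- pnorm((seq_len(nr) - y0) / sy) - pnorm((seq_len(nr) - 1 - y0) / sy)
  offset + A * outer(gy, gx)
}

#' Fit an axis-aligned elliptical Gaussian to a spot patch
#'
#' Least-squares fit of a pixel-integrated 2D Gaussian with constant offset,
#' the standard localization model for astigmatic STORM (the cylindrical
#' lens aligns the ellipse with the camera axes, so no rotation term).
#' Positions and widths are in continuous pixel units of the patch; the
#' caller converts to nm. `photons = A / gain` where A is the fitted
#' integrated amplitude.
#'
#' @param patch 2D intensity matrix containing one spot.
#' @param init optional `c(x0, y0)` starting position in patch pixel
#'   coordinates (defaults to the intensity centroid).
#' @param gain camera gain in counts/photon (synthetic data is already in
#'   photons, so 1).
#' @return list of class `"spot_fit"`: `ok`, `x`, `y`, `width_x`, `width_y`
#'   (px), `amplitude`, `offset`, `photons`, `rss`. `ok = FALSE` flags a
#'   failed fit (non-convergence or collapsed widths < 0.3 px).
#' @export
fit_gaussian <- function(patch, init = NULL, gain = 1) {
  stopifnot(is.matrix(patch))
  nr <- nrow(patch); nc <- ncol(patch)
  off0 <- min(patch)
  w <- patch - off0
  tot <- sum(w)
  if (tot <= 0 || sd(as.vector(patch)) == 0)
    return(structure(list(ok = FALSE, reason = "flat patch"), class = "spot_fit"))
  cx <- sum(t(w) * (seq_len(nc) - 0.5)) / tot
  cy <- sum(w * (seq_len(nr) - 0.5)) / tot
  sx0 <- sqrt(max(sum(t(w) * (seq_len(nc) - 0.5 - cx) ^ 2) / tot, 0.25))
  sy0 <- sqrt(max(sum(w * (seq_len(nr) - 0.5 - cy) ^ 2) / tot, 0.25))
  if (!is.null(init)) { cx <- init[1]; cy <- init[2] }
  par0 <- c(cx, cy, log(sx0), log(sy0), log(tot), off0)
  obj <- function(p) {
    mu <- .gauss_patch(nr, nc, p[1], p[2], exp(p[3]), exp(p[4]), exp(p[5]), p[6])
    sum((patch - mu) ^ 2)
  }
  fit <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  p <- fit$par
  sx <- exp(p[3]); sy <- exp(p[4])
  ok <- fit$convergence == 0 && sx >= 0.3 && sy >= 0.3 &&
    p[1] > 0 && p[1] < nc && p[2] > 0 && p[2] < nr
  structure(list(ok = ok, x = p[1], y = p[2], width_x = sx, width_y = sy,
                 amplitude = exp(p[5]), offset = p[6],
                 photons = exp(p[5]) / gain, rss = fit$value),
            class = "spot_fit")
}

#' Localize an image stack into a table of detections
#'
#' Runs [detect_spots()] and [fit_gaussian()] over every frame and converts
#' fits to nm using the stack pixel size. With a calibration curve, each
#' detection's (wx, wy) is turned into z by [z_lookup()]; detections whose
#' widths no point of the calibration explains are dropped.
#'
#' @param stack an [image_stack()].
#' @param threshold detection threshold in counts.
#' @param min_separation suppression radius in px.
#' @param patch_half half-size of the fit patch (default 3, i.e. 7x7 px).
#' @param calibration optional `"calibration_curve"` for 3D.
#' @param gain counts per photon.
#' @param channel channel label for the output table.
#' @param z_cutoff rejection cutoff passed to [z_lookup()].
#' @return a [localization_table()].
#' @export
localize_stack <- function(stack, threshold, min_separation = 3,
                           patch_half = 3, calibration = NULL, gain = 1,
                           channel = "647", z_cutoff = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  ps <- stack$pixel_size_nm
  rows <- list()
  for (k in seq_len(dim(stack$frames)[1])) {
    fr <- stack$frames[k, , ]
    cand <- detect_spots(fr, threshold, min_separation)
    for (i in seq_len(nrow(cand))) {
      r0 <- cand$row[i]; c0 <- cand$col[i]
      if (r0 - patch_half < 1 || r0 + patch_half > nrow(fr) ||
          c0 - patch_half < 1 || c0 + patch_half > ncol(fr)) next
      patch <- fr[(r0 - patch_half):(r0 + patch_half),
                  (c0 - patch_half):(c0 + patch_half)]
      f <- fit_gaussian(patch, gain = gain)
      if (!isTRUE(f$ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        x = (c0 - patch_half - 1 + f$x) * ps,
        y = (r0 - patch_half - 1 + f$y) * ps,
        frame = stack$frame_index[k],
        photons = f$photons,
        width_x = f$width_x * ps, width_y = f$width_y * ps)
    }
  }
  if (!length(rows))
    return(localization_table(numeric(0), numeric(0), channel = channel))
  tab <- do.call(rbind, rows)
  tab$channel <- channel
  if (!is.null(calibration)) {
    z <- z_lookup(tab$width_x, tab$width_y, calibration, cutoff = z_cutoff)
    tab$z <- z
    tab <- tab[!is.na(z), , drop = FALSE]
  }
  rownames(tab) <- NULL
  validate_localizations(tab)
}
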