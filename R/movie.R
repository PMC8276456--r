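#' Render a synthetic STORM movie with fiducial bead frames
#'
#' Turns a ground-truth localization table into camera frames: each
#' localization is rendered in its frame as a pixel-integrated elliptical
#' Gaussian whose widths come from the astigmatic calibration at its true z
#' (or the in-focus width for 2D tables), Poisson photon noise and a
#' constant background are applied, and the injected drift shifts both the
#' emitters and a set of bright fiducial bead images sampled every
#' `bead_interval` frames (the last movie frame is always sampled, so the
#' bead trace covers the full frame range).
#'
#' @param table localization table holding the true emitter positions (nm),
#'   frames and photon counts (`NA` photons fall back to `photon_mean`).
#' @param calibration optional `"calibration_curve"` used to render
#'   z-dependent widths; required when the table has a z column. An emitter
#'   z outside the calibrated range is an error naming the row.
#' @param drift optional [drift_trace()] in nm (default: no drift).
#' @param photon_mean default photons per emitter.
#' @param background expected background counts per pixel per frame.
#' @param n_frames movie length (default: one past the table's last frame).
#' @param camera list with `nx`, `ny` (px) and `pixel_size_nm`.
#' @param bead_positions m x 2 matrix of bead positions in nm (default: 3
#'   beads spread over the field).
#' @param bead_interval movie frames between bead snapshots.
#' @param bead_photons photons per bead spot.
#' @param seed integer seed for the Poisson noise.
#' @return list with `movie` ([image_stack()]), `beads` (an `image_stack`
#'   with `frame_index` at the snapshot frames), and `truth` (drift trace
#'   and bead positions).
#' @export
simulate_movie <- function(table, calibration = NULL, drift = NULL,
                           photon_mean = 3000, background = 5,
                           n_frames = NULL,
                           camera = list(nx = 64, ny = 64, pixel_size_nm = 160),
                           bead_positions = NULL, bead_interval = 100,
                           bead_photons = 5e4, seed = 1L) {
  table <- validate_localizations(table)
  ps <- camera$pixel_size_nm
  if (is.null(n_frames)) n_frames <- max(table$frame) + 1L
  if (is.null(drift)) drift <- drift_trace(c(0L, max(n_frames - 1L, 1L)), c(0, 0), c(0, 0))
  set.seed(seed)
  w0 <- 150
  if (!is.null(table$z)) {
    if (is.null(calibration)) stop("3D table needs a calibration curve to render widths")
    bad <- which(table$z < calibration$range[1] | table$z > calibration$range[2])
    if (length(bad))
      stop("emitter in row ", bad[1], " has z = ", round(table$z[bad[1]]),
           " nm outside the calibrated range")
    w <- predict_widths(calibration, table$z)
    sx <- w$wx / ps; sy <- w$wy / ps
  } else {
    sx <- rep(w0 / ps, nrow(table)); sy <- rep(w0 / ps, nrow(table))
  }
  photons <- ifelse(is.na(table$photons), photon_mean, table$photons)
  dloc <- drift_at(drift, table$frame)
  px <- (table$x + dloc[, "dx"]) / ps
  py <- (table$y + dloc[, "dy"]) / ps

  mov <- array(background, c(n_frames, camera$ny, camera$nx))
  add_spot <- function(arr, k, x0, y0, sx, sy, A) {
    hw <- ceiling(4 * max(sx, sy)) + 1
    c1 <- max(1, floor(x0) - hw); c2 <- min(camera$nx, ceiling(x0) + hw)
    r1 <- max(1, floor(y0) - hw); r2 <- min(camera$ny, ceiling(y0) + hw)
    if (c1 > c2 || r1 > r2) return(arr)
    gx <- pnorm((c1:c2 - x0) / sx) - pnorm((c1:c2 - 1 - x0) / sx)
    gy <- pnorm((r1:r2 - y0) / sy) - pnorm((r1:r2 - 1 - y0) / sy)
    arr[k, r1:r2, c1:c2] <- arr[k, r1:r2, c1:c2] + A * outer(gy, gx)
    arr
  }
  for (i in seq_len(nrow(table)))
    mov <- add_spot(mov, table$frame[i] + 1L, px[i], py[i], sx[i], sy[i], photons[i])
  mov[] <- rpois(length(mov), mov)

  if (is.null(bead_positions)) {
    fx <- camera$nx * ps; fy <- camera$ny * ps
    bead_positions <- rbind(c(0.2 * fx, 0.25 * fy), c(0.75 * fx, 0.3 * fy),
                            c(0.4 * fx, 0.8 * fy))
  }
  bead_frames <- unique(c(seq(0L, n_frames - 1L, by = bead_interval), n_frames - 1L))
  beads <- array(background, c(length(bead_frames), camera$ny, camera$nx))
  for (k in seq_along(bead_frames)) {
    db <- drift_at(drift, bead_frames[k])
    for (b in seq_len(nrow(bead_positions)))
      beads <- add_spot(beads, k,
                        (bead_positions[b, 1] + db[1, "dx"]) / ps,
                        (bead_positions[b, 2] + db[1, "dy"]) / ps,
                        2, 2, bead_photons)
  }
  beads[] <- rpois(length(beads), beads)
  list(movie = image_stack(mov, ps),
       beads = image_stack(beads, ps, frame_index = bead_frames),
       truth = list(drift = drift, bead_positions = bead_positions, seed = seed))
}
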