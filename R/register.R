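#' Drift traces
#'
#' A drift trace records the lateral stage displacement (dx, dy) in nm at a
#' set of anchor frames, relative to the first anchor; displacement at
#' intermediate frames is obtained by linear interpolation. Traces produced
#' by [estimate_drift()] have a (0, 0) first-block displacement by
#' construction; hand-built traces (a constant offset, say) apply as given.
#'
#' @param frame 0-based anchor frame indices (strictly increasing).
#' @param dx,dy displacements in nm at the anchors.
#' @return data frame of class `"drift_trace"`.
#' @export
drift_trace <- function(frame, dx, dy) {
  stopifnot(length(frame) == length(dx), length(dx) == length(dy),
            !is.unsorted(frame, strictly = TRUE))
  tr <- data.frame(frame = as.integer(frame), dx = dx, dy = dy)
  class(tr) <- c("drift_trace", "data.frame")
  tr
}

#' Linear drift helper (mostly for simulations)
#' @param total_dx,total_dy endpoint displacement in nm over the movie.
#' @param n_frames number of movie frames.
#' @param n_anchors number of anchor points along the trace.
#' @return a [drift_trace()].
#' @export
linear_drift <- function(total_dx, total_dy, n_frames, n_anchors = 21) {
  f <- unique(round(seq(0, n_frames - 1, length.out = n_anchors)))
  s <- f / (n_frames - 1)
  drift_trace(f, total_dx * s, total_dy * s)
}

#' Evaluate a drift trace at arbitrary frames
#' @param trace a [drift_trace()].
#' @param frames frame indices; must lie inside the trace's anchor range.
#' @return 2-column matrix of (dx, dy) in nm.
#' @export
drift_at <- function(trace, frames) {
  stopifnot(inherits(trace, "drift_trace"))
  if (any(frames < min(trace$frame) | frames > max(trace$frame)))
    stop("frame outside drift-trace range [", min(trace$frame), ", ",
         max(trace$frame), "]")
  if (nrow(trace) == 1) return(cbind(dx = rep(trace$dx, length(frames)),
                                     dy = rep(trace$dy, length(frames))))
  cbind(dx = approx(trace$frame, trace$dx, xout = frames)$y,
        dy = approx(trace$frame, trace$dy, xout = frames)$y)
}

# FFT cross-correlation shift of image b relative to image a, in px,
# with 3-point parabolic sub-pixel interpolation around the peak.
.xcorr_shift <- function(a, b) {
  Fa <- fft(a); Fb <- fft(b)
  cc <- Re(fft(Conj(Fa) * Fb, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(a); nc <- ncol(a)
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else 0.5 * (cm - cp) / den
  }
  r <- unname(pk[1]); c <- unname(pk[2])
  rp <- r %% nr + 1; rm <- (r - 2) %% nr + 1
  cp <- c %% nc + 1; cm <- (c - 2) %% nc + 1
  dr <- (r - 1) + para(cc[rm, c], cc[r, c], cc[rp, c])
  dc <- (c - 1) + para(cc[r, cm], cc[r, c], cc[r, cp])
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  c(dx = dc, dy = dr)
}

#' Estimate stage drift from fiducial bead images
#'
#' Bead snapshots are grouped into blocks of `block_size` movie frames,
#' averaged within each block, and each block image is cross-correlated
#' against the first block (FFT correlation with parabolic sub-pixel peak
#' interpolation). The resulting per-block displacements, converted to nm,
#' form the drift trace anchored at each block's first snapshot frame.
#'
#' @param bead_stack an [image_stack()] of fiducial images with
#'   `frame_index` giving each snapshot's movie frame.
#' @param block_size block length in movie frames (default 500).
#' @return a [drift_trace()].
#' @export
estimate_drift <- function(bead_stack, block_size = 500) {
  stopifnot(inherits(bead_stack, "image_stack"))
  blocks <- bead_stack$frame_index %/% block_size
  ub <- sort(unique(blocks))
  if (length(ub) < 2) stop("need at least 2 blocks of bead images")
  imgs <- list(); anchor <- integer(length(ub))
  for (i in seq_along(ub)) {
    sel <- which(blocks == ub[i])
    m <- apply(bead_stack$frames[sel, , , drop = FALSE], c(2, 3), mean)
    if (sd(as.vector(m)) == 0)
      stop("featureless bead image in block ", ub[i], ": cannot cross-correlate")
    imgs[[i]] <- m
    anchor[i] <- round(mean(bead_stack$frame_index[sel]))
  }
  # pin the end anchors to the snapshot range so the trace covers the movie
  anchor[1] <- min(bead_stack$frame_index)
  anchor[length(anchor)] <- max(bead_stack$frame_index)
  ps <- bead_stack$pixel_size_nm
  sh <- t(vapply(imgs, function(m) .xcorr_shift(imgs[[1]], m), numeric(2)))
  drift_trace(anchor, sh[, "dx"] * ps, sh[, "dy"] * ps)
}

#' Subtract drift from a localization table
#'
#' Each localization is shifted by minus the interpolated drift at its
#' frame. Row order and all non-coordinate columns are preserved exactly; a
#' zero trace is the identity.
#'
#' @param table a [localization_table()].
#' @param trace a [drift_trace()] covering all frames in the table.
#' @return the corrected table.
#' @export
apply_drift <- function(table, trace) {
  table <- validate_localizations(table)
  if (!nrow(table)) return(table)
  d <- drift_at(trace, table$frame)
  table$x <- table$x - d[, "dx"]
  table$y <- table$y - d[, "dy"]
  table
}

#' Register one channel onto another from matched control points
#'
#' Least-squares transform mapping channel-2 coordinates onto channel 1.
#' `"translation"` (default; rigid inter-channel drift, as measured from
#' interlaced bright-field fiducials) needs one pair or more; `"affine"`
#' (chromatic scaling/shear) needs at least 3 non-collinear pairs.
#'
#' @param reference_points_ch1,reference_points_ch2 n x 2 matrices of
#'   matched (x, y) in nm.
#' @param mode `"translation"` or `"affine"`.
#' @return list of class `"channel_transform"`: `mode`, `params` (length-2
#'   offset, or 2x3 matrix `[A | b]`), and `residual_nm` (RMS over points).
#' @export
register_channels <- function(reference_points_ch1, reference_points_ch2,
                              mode = c("translation", "affine")) {
  mode <- match.arg(mode)
  p1 <- as.matrix(reference_points_ch1); p2 <- as.matrix(reference_points_ch2)
  stopifnot(ncol(p1) == 2, ncol(p2) == 2, nrow(p1) == nrow(p2), nrow(p1) >= 1)
  if (mode == "translation") {
    off <- colMeans(p1 - p2)
    pred <- sweep(p2, 2, off, `+`)
    params <- off
  } else {
    if (nrow(p1) < 3) stop("affine registration needs at least 3 control points")
    X <- cbind(p2, 1)
    if (qr(X)$rank < 3) stop("control points are collinear: affine transform is degenerate")
    beta <- qr.solve(X, p1)          # 3 x 2
    pred <- X %*% beta
    params <- t(beta)                # 2 x 3: [A | b]
  }
  structure(list(mode = mode, params = params,
                 residual_nm = sqrt(mean(rowSums((pred - p1) ^ 2)))),
            class = "channel_transform")
}

#' Apply a channel transform to coordinates
#' @param transform a `"channel_transform"`.
#' @param xy n x 2 matrix or a localization table (x/y columns updated).
#' @return same type as `xy`, transformed onto the reference channel.
#' @export
apply_transform <- function(transform, xy) {
  stopifnot(inherits(transform, "channel_transform"))
  tab <- NULL
  if (is.data.frame(xy)) { tab <- xy; xy <- cbind(tab$x, tab$y) }
  out <- if (transform$mode == "translation") {
    sweep(xy, 2, transform$params, `+`)
  } else {
    t(transform$params %*% t(cbind(xy, 1)))
  }
  if (is.null(tab)) return(out)
  tab$x <- out[, 1]; tab$y <- out[, 2]
  tab
}
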