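#' Camera image stacks
#'
#' A thin container for a movie of camera frames: a 3D array indexed
#' `[frame, row, col]` plus the pixel size in nm. The coordinate convention
#' ties pixel and physical space together: a continuous position of u pixels
#' corresponds to u * pixel_size nm, so the center of pixel (0,0) sits at
#' (pixel_size/2, pixel_size/2) nm. Columns advance x, rows advance y.
#'
#' @param frames 3D numeric array `[frame, row, col]` (a matrix is promoted
#'   to a single-frame stack). Intensities must be non-negative.
#' @param pixel_size_nm pixel pitch in nm (default 160, a common EMCCD
#'   geometry at 100x magnification).
#' @param frame_index optional 0-based movie-frame index of each stack frame
#'   (used when a stack holds interleaved fiducial snapshots).
#' @return an object of class `"image_stack"`.
#' @export
image_stack <- function(frames, pixel_size_nm = 160, frame_index = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(1L, nrow(frames), ncol(frames)))
  stopifnot(length(dim(frames)) == 3, pixel_size_nm > 0)
  if (any(frames < 0)) stop("negative intensity in image stack")
  if (is.null(frame_index)) frame_index <- seq_len(dim(frames)[1]) - 1L
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 frame_index = as.integer(frame_index)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frame(s) of %d x %d px, %.0f nm/px\n",
              d[1], d[2], d[3], x$pixel_size_nm))
  invisible(x)
}

#' Read a TIFF stack
#'
#' @param path TIFF file path.
#' @param pixel_size_nm pixel pitch to attach (TIFF tags are not relied on).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_nm = 160) {
  fr <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(fr)) fr <- list(fr)
  arr <- array(0, c(length(fr), nrow(fr[[1]]), ncol(fr[[1]])))
  for (i in seq_along(fr)) arr[i, , ] <- fr[[i]]
  image_stack(arr, pixel_size_nm)
}

#' Write a TIFF stack (32-bit float)
#'
#' Intensities are scaled to `[0, 1]` by the stack maximum before writing,
#' with the scale recorded in nothing: this writer exists for visual
#' inspection, not quantitative round-trips (use the localization CSVs for
#' those).
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @export
write_image_stack <- function(stack, path) {
  mx <- max(stack$frames, 1e-12)
  fr <- lapply(seq_len(dim(stack$frames)[1]),
               function(i) stack$frames[i, , ] / mx)
  tiff::writeTIFF(fr, path, bits.per.sample = 32L)
  invisible(path)
}
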