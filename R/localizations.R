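#' Build a localization table
#'
#' The central data structure of the package: one row per single-molecule
#' detection, coordinates in nanometres. Every localization is treated
#' downstream as a point of unit mass, so all cluster statistics (barycenter,
#' radius of gyration, ...) are unweighted moments of these rows.
#'
#' @param x,y lateral coordinates in nm.
#' @param z optional axial coordinate in nm (astigmatism-derived).
#' @param frame 0-based acquisition frame index.
#' @param channel channel label (free string, e.g. `"647"` or `"561"`).
#' @param photons photon count of the detection (`NA` if unknown).
#' @param width_x,width_y fitted PSF widths (Gaussian sigma) in nm, optional.
#' @param uncertainty_xy optional lateral localization uncertainty in nm.
#' @return a `data.frame` of class `"loc_table"`.
#' @export
localization_table <- function(x, y, z = NULL, frame = 0L, channel = "647",
                               photons = NA_real_, width_x = NULL,
                               width_y = NULL, uncertainty_xy = NULL) {
  n <- length(x)
  tab <- data.frame(
    x = as.numeric(x), y = as.numeric(y),
    frame = as.integer(rep_len(frame, n)),
    channel = as.character(rep_len(channel, n)),
    photons = as.numeric(rep_len(photons, n)),
    stringsAsFactors = FALSE
  )
  if (!is.null(z)) tab$z <- as.numeric(rep_len(z, n))
  if (!is.null(width_x)) tab$width_x <- as.numeric(rep_len(width_x, n))
  if (!is.null(width_y)) tab$width_y <- as.numeric(rep_len(width_y, n))
  if (!is.null(uncertainty_xy)) tab$uncertainty_xy <- as.numeric(rep_len(uncertainty_xy, n))
  class(tab) <- c("loc_table", "data.frame")
  validate_localizations(tab)
}

#' Validate a localization table
#'
#' Checks the structural invariants: finite coordinates, non-negative frames
#' and photon counts, strictly positive fitted widths where present.
#'
#' @param tab a data frame with at least `x`, `y`, `frame` columns.
#' @return the validated table (invisibly classed as `loc_table`).
#' @export
validate_localizations <- function(tab) {
  for (col in c("x", "y", "frame")) {
    if (is.null(tab[[col]])) stop("localization table lacks mandatory column '", col, "'")
  }
  if (nrow(tab)) {
    if (!all(is.finite(tab$x)) || !all(is.finite(tab$y)))
      stop("non-finite x/y coordinate in localization table")
    if (!is.null(tab$z) && !all(is.finite(tab$z)))
      stop("non-finite z coordinate in localization table")
    if (any(tab$frame < 0)) stop("negative frame index")
    if (!is.null(tab$photons) && any(tab$photons < 0, na.rm = TRUE))
      stop("negative photon count")
    for (w in c("width_x", "width_y")) {
      if (!is.null(tab[[w]]) && any(tab[[w]] <= 0, na.rm = TRUE))
        stop("non-positive fitted width in column '", w, "'")
    }
  }
  if (!inherits(tab, "loc_table")) class(tab) <- c("loc_table", "data.frame")
  tab
}

# column-name maps per CSV dialect; unit suffixes like "x [nm]" are stripped
# before lookup, so the ThunderSTORM export header maps straight onto native
# names. ThunderSTORM frames are 1-based and shifted to 0-based on read.
.ts_name_map <- c(
  x = "x", y = "y", z = "z", frame = "frame", id = "id",
  sigma = "width_x", sigma1 = "width_x", sigma2 = "width_y",
  intensity = "photons", uncertainty = "uncertainty_xy",
  uncertainty_xy = "uncertainty_xy", channel = "channel",
  photons = "photons", width_x = "width_x", width_y = "width_y"
)

#' Read a localization table from CSV
#'
#' Two dialects are accepted: the package's native header
#' (`x,y,frame,channel,photons,...`, all lengths in nm) and a
#' ThunderSTORM-style header in which columns carry unit brackets
#' (`"x [nm]"`, `"sigma1 [nm]"`, `"intensity [photon]"`) and frames are
#' 1-based. All coordinates are returned in nm with 0-based frames.
#'
#' @param path CSV file path.
#' @param dialect `"native_csv"` or `"thunderstorm_csv"`.
#' @return a validated [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("native_csv", "thunderstorm_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  stringsAsFactors = FALSE)
  nm <- trimws(sub("\\[.*\\]", "", names(raw)))  # "x [nm]" -> "x"
  mapped <- .ts_name_map[nm]
  keep <- !is.na(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]
  for (col in c("x", "y")) {
    if (is.null(raw[[col]])) stop("schema error: mandatory column '", col, "' missing in ", path)
  }
  num_cols <- intersect(names(raw),
                        c("x", "y", "z", "frame", "photons", "width_x",
                          "width_y", "uncertainty_xy", "id"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    if (length(bad))
      stop("parse error: non-numeric value '", raw[[col]][bad[1]], "' in column '",
           col, "', row ", bad[1])
    raw[[col]] <- v
  }
  if (is.null(raw$frame)) raw$frame <- 0
  if (dialect == "thunderstorm_csv") raw$frame <- raw$frame - 1
  if (is.null(raw$channel)) raw$channel <- "647"
  if (is.null(raw$photons)) raw$photons <- NA_real_
  raw$frame <- as.integer(round(raw$frame))
  raw$id <- NULL
  validate_localizations(raw)
}

#' Write a localization table to CSV
#'
#' Numeric columns are serialized with 17 significant digits so a
#' read/write cycle is bit-identical on IEEE doubles.
#'
#' @param tab a validated localization table.
#' @param path output CSV path.
#' @export
write_localizations <- function(tab, path) {
  tab <- validate_localizations(tab)
  out <- as.data.frame(tab)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      s <- sprintf("%.17g", out[[col]])
      s[is.na(out[[col]])] <- "NA"
      out[[col]] <- s
    }
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write localization table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
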