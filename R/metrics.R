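#' Barycenter of a set of localizations
#'
#' Every localization carries unit mass, so the barycenter is the plain
#' coordinate-wise mean.
#'
#' @param members localization table (or any data frame with x/y(/z)).
#' @param dims `"2d"` or `"3d"`.
#' @return named numeric vector (nm).
#' @export
barycenter <- function(members, dims = "2d") {
  P <- .coord_matrix(members, dims)
  if (!nrow(P)) stop("cannot take the barycenter of an empty set")
  setNames(colMeans(P), c("x", "y", "z")[seq_len(ncol(P))])
}

#' Radius of gyration
#'
#' Root-mean-square distance of the localizations from their barycenter,
#' `Rg^2 = (1/N) * sum_i |r_i - rbar|^2`, over the selected dimensions.
#'
#' @inheritParams barycenter
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(members, dims = "2d") {
  P <- .coord_matrix(members, dims)
  if (!nrow(P)) stop("cannot compute Rg of an empty set")
  ctr <- colMeans(P)
  sqrt(mean(rowSums(sweep(P, 2, ctr) ^ 2)))
}

#' Metrics of a segmented cluster
#'
#' The exported per-cluster quantities: detection count, barycenter, radius
#' of gyration, major axis (defined as 4 sigma along the first principal
#' component of the member coordinates, i.e. the ~95% extent of a Gaussian
#' cluster; half of it is the sampling radius R of the random null),
#' diameter (maximum pairwise distance) and density (detections per
#' convex-hull area in localizations/um^2, or per ellipsoid-equivalent
#' volume in 3D). A single-point cluster has zero major axis and diameter
#' and undefined density.
#'
#' @param members localization table subset belonging to one cluster.
#' @param dims `"2d"` or `"3d"`.
#' @param indices optional original row indices to carry along.
#' @return list of class `"storm_cluster"`.
#' @export
cluster_metrics <- function(members, dims = "2d", indices = NULL) {
  P <- .coord_matrix(members, dims)
  n <- nrow(P)
  if (n < 1) stop("cluster must have at least one member")
  ctr <- colMeans(P)
  rg <- sqrt(mean(rowSums(sweep(P, 2, ctr) ^ 2)))
  if (n == 1) {
    major <- 0; diam <- 0; density <- NA_real_
  } else {
    ev <- eigen(var(P), symmetric = TRUE, only.values = TRUE)$values
    major <- 4 * sqrt(max(ev[1], 0))
    diam <- .max_pairwise(P)
    hm <- .hull_measure(P)
    scale <- if (ncol(P) == 2) 1e6 else 1e9      # nm^2 -> um^2, nm^3 -> um^3
    density <- if (hm > 0) n / hm * scale else NA_real_
  }
  structure(list(indices = indices, n = n,
                 barycenter = setNames(ctr, c("x", "y", "z")[seq_len(ncol(P))]),
                 rg = rg, major_axis = major, diameter = diam,
                 density = density, dims = dims),
            class = "storm_cluster")
}

.max_pairwise <- function(P) {
  n <- nrow(P)
  if (ncol(P) == 2 && n > 50) {
    P <- P[chull(P), , drop = FALSE]       # 2D diameter is attained on the hull
  } else if (n > 3000) {
    # extreme points along a fan of directions bound the diameter well
    ang <- seq(0, pi, length.out = 13)[-13]
    dirs <- if (ncol(P) == 2) cbind(cos(ang), sin(ang)) else {
      u <- matrix(rnorm(3 * 40), ncol = 3); u / sqrt(rowSums(u ^ 2))
    }
    proj <- P %*% t(dirs)
    keep <- unique(c(apply(proj, 2, which.min), apply(proj, 2, which.max)))
    P <- P[keep, , drop = FALSE]
  }
  max(dist(P))
}

#' @export
print.storm_cluster <- function(x, ...) {
  cat(sprintf("cluster: %d detections, Rg %.1f nm, major axis %.1f nm, diameter %.1f nm\n",
              x$n, x$rg, x$major_axis, x$diameter))
  invisible(x)
}

#' Tabulate a list of clusters
#'
#' @param clusters list of `"storm_cluster"` objects.
#' @return data frame with one row per cluster (detections, barycenter,
#'   Rg, major axis, diameter, density).
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster = integer(0), n = integer(0), bx = numeric(0),
                      by = numeric(0), rg = numeric(0), major_axis = numeric(0),
                      diameter = numeric(0), density = numeric(0)))
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, n = cl$n, bx = cl$barycenter["x"],
               by = cl$barycenter["y"],
               bz = if (length(cl$barycenter) > 2) cl$barycenter["z"] else NA_real_,
               rg = cl$rg, major_axis = cl$major_axis, diameter = cl$diameter,
               density = cl$density, row.names = NULL)
  }))
}
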