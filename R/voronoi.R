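#' Voronoi-density segmentation of a 2D localization field
#'
#' The SR-Tesseler approach: build the Voronoi tessellation of the
#' localizations, define each point's first-rank density as the inverse of
#' its cell area, and select points whose density exceeds `density_factor`
#' times the global mean density (total points / convex-hull area of the
#' field). Selected points whose Voronoi cells share an edge are merged
#' into clusters; clusters with fewer than `min_detections` members are
#' dropped. Cells on the tessellation boundary (clipped, effectively
#' unbounded) carry no meaningful density and are never selected.
#'
#' Density factors in routine use: 3 for chromatin domains / TADs, 20 for
#' replication origins or initiation foci, 3.5 for protein clusters.
#'
#' @param table localization table (2D; x/y used).
#' @param density_factor multiple of the mean density a cell must exceed.
#' @param min_detections minimum localizations per reported cluster.
#' @return list: `labels` (0 = unclustered), `clusters` (row-index
#'   vectors, ordered by decreasing size), `mean_density` (per nm^2),
#'   `density_factor`.
#' @export
voronoi_density_segment <- function(table, density_factor = 3,
                                    min_detections = 10) {
  stopifnot(density_factor > 0)
  x <- table$x; y <- table$y
  n <- length(x)
  if (n < 4) stop("Voronoi segmentation needs at least 4 points")
  if (abs(cor(x, y)) > 1 - 1e-12 || sd(x) == 0 || sd(y) == 0)
    stop("all points are collinear: Voronoi tessellation is degenerate")
  dup <- duplicated(cbind(x, y))
  ux <- x[!dup]; uy <- y[!dup]
  orig <- which(!dup)
  pad <- 0.05 * c(diff(range(ux)), diff(range(uy)))
  rw <- c(min(ux) - pad[1], max(ux) + pad[1], min(uy) - pad[2], max(uy) + pad[2])
  dd <- deldir::deldir(ux, uy, rw = rw, suppressMsge = TRUE)
  area <- dd$summary$dir.area
  boundary <- dd$summary$nbpt > 0
  hull <- chull(cbind(ux, uy))
  mean_density <- length(ux) / .polygon_area(cbind(ux, uy)[hull, , drop = FALSE])
  selected <- !boundary & area > 0 & (1 / area) > density_factor * mean_density

  m <- length(ux)
  parent <- seq_len(m)
  sg <- dd$dirsgs
  adj <- sg[selected[sg$ind1] & selected[sg$ind2], c("ind1", "ind2")]
  for (e in seq_len(nrow(adj))) {
    ri <- .uf_find(parent, adj$ind1[e]); rj <- .uf_find(parent, adj$ind2[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  labels_u <- integer(m)
  sel_idx <- which(selected)
  if (length(sel_idx)) {
    roots <- vapply(sel_idx, function(i) .uf_find(parent, i), integer(1))
    comp <- split(sel_idx, roots)
    comp <- comp[vapply(comp, length, integer(1)) >= min_detections]
    comp <- comp[order(-vapply(comp, length, integer(1)))]
    for (ci in seq_along(comp)) labels_u[comp[[ci]]] <- ci
  }
  labels <- integer(n)
  labels[orig] <- labels_u
  if (any(dup)) {
    # duplicated coordinates inherit the label of their retained twin
    key <- paste(x, y, sep = "_")
    labels[dup] <- labels[orig][match(key[dup], key[orig])]
  }
  k <- max(labels, 0)
  clusters <- if (k) lapply(seq_len(k), function(ci) which(labels == ci)) else list()
  list(labels = labels, clusters = clusters, mean_density = mean_density,
       density_factor = density_factor)
}
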