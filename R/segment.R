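#' DBSCAN parameters (two-radius variant)
#'
#' The segmentation used here generalizes textbook DBSCAN to two radii:
#' a localization is a *core point* when at least `n_min` other
#' localizations lie within the neighbor radius `r`; core points closer
#' than the reference distance `r_ref` belong to the same cluster; and
#' *border points* are non-core localizations within `r_ref` of a cluster's
#' core points. `r_ref` defaults to `r`, which recovers ordinary DBSCAN.
#'
#' @param r neighbor-count radius in nm.
#' @param n_min core threshold: minimum neighbors within `r` (self excluded).
#' @param r_ref connectivity/border radius in nm (default `r`).
#' @return list of class `"dbscan_params"`.
#' @export
dbscan_params <- function(r, n_min, r_ref = r) {
  stopifnot(r > 0, r_ref > 0, n_min >= 1)
  structure(list(r = r, n_min = as.integer(n_min), r_ref = r_ref),
            class = "dbscan_params")
}

# union-find with path halving
.uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

# neighbor lists within radius R by grid binning: returns list of
# data.frames (j, d) per point, self excluded
.radius_neighbors <- function(P, R) {
  n <- nrow(P); d <- ncol(P)
  cells <- floor(sweep(P, 2, rep(R, d), `/`))
  key <- do.call(paste, c(as.data.frame(cells), sep = "_"))
  cell_map <- split(seq_len(n), key)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  out <- vector("list", n)
  for (k in names(cell_map)) {
    pts <- cell_map[[k]]
    base <- cells[pts[1], ]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nk <- paste(base + offs[o, ], collapse = "_")
      cand <- c(cand, cell_map[[nk]])
    }
    D2 <- outer(rowSums(P[pts, , drop = FALSE] ^ 2),
                rowSums(P[cand, , drop = FALSE] ^ 2), `+`) -
      2 * P[pts, , drop = FALSE] %*% t(P[cand, , drop = FALSE])
    D <- sqrt(pmax(D2, 0))
    for (a in seq_along(pts)) {
      i <- pts[a]
      sel <- which(D[a, ] <= R & cand != i)
      out[[i]] <- list(j = cand[sel], d = pmax(D[a, sel], 0))
    }
  }
  out
}

#' Cluster a localization table with two-radius DBSCAN
#'
#' Core points have >= `n_min` neighbors within `r` (self excluded); core
#' points at distance < `r_ref` are connected into one cluster; border
#' points are attached when within `r_ref` (inclusive) of a cluster's core
#' points, and a border point reachable from several clusters goes to the
#' cluster of its nearest core point (ties to the lower cluster index).
#' Everything else is noise. Cluster indices are ordered by each cluster's
#' smallest core-point row index, so the labeling is reproducible.
#'
#' @param table a [localization_table()] (or data frame with x/y(/z)).
#' @param params a [dbscan_params()].
#' @param dims `"2d"` (x, y) or `"3d"` (x, y, z).
#' @return list: `labels` (integer per row, 0 = noise), `clusters` (list of
#'   row-index vectors), `core` (logical per row), `params`.
#' @export
dbscan_clusters <- function(table, params, dims = "2d") {
  stopifnot(inherits(params, "dbscan_params"))
  P <- .coord_matrix(table, dims)
  n <- nrow(P)
  if (n == 0)
    return(list(labels = integer(0), clusters = list(), core = logical(0),
                params = params))
  nbr <- .radius_neighbors(P, max(params$r, params$r_ref))
  count_r <- vapply(nbr, function(e) sum(e$d <= params$r), integer(1))
  core <- count_r >= params$n_min
  parent <- seq_len(n)
  for (i in which(core)) {
    e <- nbr[[i]]
    for (j in e$j[core[e$j] & e$d < params$r_ref]) {
      ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  labels <- integer(n)
  roots <- vapply(which(core), function(i) .uf_find(parent, i), integer(1))
  if (length(roots)) {
    uroots <- sort(unique(roots))           # root = smallest core index
    labels[which(core)] <- match(roots, uroots)
  }
  for (i in which(!core)) {
    e <- nbr[[i]]
    sel <- e$j[core[e$j] & e$d <= params$r_ref]
    if (!length(sel)) next
    dd <- e$d[match(sel, e$j)]
    best <- sel[dd == min(dd)]
    labels[i] <- min(labels[best])
  }
  k <- max(labels, 0)
  clusters <- if (k) lapply(seq_len(k), function(ci) which(labels == ci)) else list()
  list(labels = labels, clusters = clusters, core = core, params = params)
}

.coord_matrix <- function(table, dims = "2d") {
  dims <- match.arg(dims, c("2d", "3d"))
  if (dims == "3d") {
    if (is.null(table$z)) stop("3d analysis requested but table has no z column")
    cbind(table$x, table$y, table$z)
  } else cbind(table$x, table$y)
}

#' Derive DBSCAN thresholds from the data
#'
#' Scale-aware defaults when no thresholds are given: `r` (and `r_ref`) is
#' three times the 5th percentile of nearest-neighbor distances, and
#' `n_min` is the neighbor count expected within `r` under the global mean
#' density (localizations / convex-hull area), floored at 4. All three are
#' echoed with [message()].
#'
#' @param table localization table with at least 10 rows.
#' @param dims `"2d"` or `"3d"`.
#' @return a [dbscan_params()].
#' @export
auto_thresholds <- function(table, dims = "2d") {
  P <- .coord_matrix(table, dims)
  n <- nrow(P)
  if (n < 10) stop("need at least 10 localizations to derive thresholds")
  q <- if (n <= 4000) seq_len(n) else sort(sample.int(n, 1000))
  nnd <- numeric(length(q))
  for (a in seq_along(q)) {
    d2 <- rowSums(sweep(P, 2, P[q[a], ], `-`) ^ 2)
    nnd[a] <- sqrt(min(d2[-q[a]]))
  }
  r <- 3 * quantile(nnd, 0.05, names = FALSE)
  rho <- n / .hull_measure(P)
  expected <- if (ncol(P) == 2) rho * pi * r ^ 2 else rho * 4 / 3 * pi * r ^ 3
  n_min <- max(4, round(expected))
  message(sprintf("auto thresholds: r = %.2f nm, n_min = %d, r_ref = %.2f nm",
                  r, n_min, r))
  dbscan_params(r = r, n_min = n_min, r_ref = r)
}

# convex hull area (2d) or ellipsoid-equivalent volume (3d) in nm^2 / nm^3
.hull_measure <- function(P) {
  if (ncol(P) == 2) {
    h <- chull(P)
    .polygon_area(P[h, , drop = FALSE])
  } else {
    S <- var(P)
    (4 / 3) * pi * sqrt(det(5 * S))
  }
}

.polygon_area <- function(V) {
  n <- nrow(V)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(V[, 1] * V[j, 2] - V[j, 1] * V[, 2])) / 2
}
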