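# Independent O(n^2) reference for the two-radius DBSCAN contract, written
# directly from the definition: core points have >= n_min neighbors within r
# (self excluded); core points at distance < r_ref are in the same cluster
# (transitively); border points are non-core points within r_ref (inclusive)
# of a cluster's core points, assigned to the nearest core point's cluster
# (ties to the lower cluster index); everything else is noise (label 0).
# Clusters are numbered by their smallest core-point row index.
brute_dbscan <- function(P, r, n_min, r_ref = r) {
  n <- nrow(P)
  if (n == 0) return(integer(0))
  D <- as.matrix(dist(P))
  core <- (rowSums(D <= r) - 1) >= n_min
  labels <- integer(n)
  next_lab <- 0L
  for (i in which(core)) {
    if (labels[i]) next
    next_lab <- next_lab + 1L
    queue <- i
    labels[i] <- next_lab
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nb <- which(core & D[j, ] < r_ref & labels == 0L)
      labels[nb] <- next_lab
      queue <- c(queue, nb)
    }
  }
  for (i in which(!core)) {
    cand <- which(core & D[i, ] <= r_ref)
    if (!length(cand)) next
    dmin <- min(D[i, cand])
    labels[i] <- min(labels[cand[D[i, cand] == dmin]])
  }
  labels
}

# partition signature invariant to cluster relabeling: sorted list of
# sorted clustered-member vectors (noise excluded)
canonical_partition <- function(labels) {
  cl <- split(which(labels > 0), labels[labels > 0])
  cl <- lapply(cl, sort)
  unname(cl[order(vapply(cl, min, integer(1)))])
}

# uniform samples in a disk / ball of radius R (independent of the
# package's generators)
runif_disk <- function(n, R = 1) {
  r <- R * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a))
}
runif_ball <- function(n, R = 1) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u ^ 2))
  u * R * runif(n) ^ (1 / 3)
}
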