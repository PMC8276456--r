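#' Assign foci to their nearest TAD
#'
#' Each focus is paired with the TAD whose barycenter is nearest to its own
#' (ties to the lower TAD index); the pair is retained only when that
#' distance is strictly shorter than half of the TAD's major axis, the
#' membership rule that keeps only foci plausibly inside the domain.
#'
#' @param foci,tads lists of [cluster_metrics()] objects.
#' @param dims `"2d"` or `"3d"` (barycenter distance dimensionality).
#' @return data frame with one row per focus: `focus`, `tad`,
#'   `distance_nm`, `assigned`.
#' @export
assign_foci <- function(foci, tads, dims = "2d") {
  nd <- if (dims == "3d") 3 else 2
  out <- data.frame(focus = seq_along(foci), tad = NA_integer_,
                    distance_nm = NA_real_, assigned = FALSE)
  if (!length(tads) || !length(foci)) return(out)
  tb <- t(vapply(tads, function(t) t$barycenter[seq_len(nd)], numeric(nd)))
  for (i in seq_along(foci)) {
    fb <- foci[[i]]$barycenter[seq_len(nd)]
    d <- sqrt(colSums((t(tb) - fb) ^ 2))
    j <- which.min(d)                       # which.min takes the lower index on ties
    out$tad[i] <- j
    out$distance_nm[i] <- d[j]
    out$assigned[i] <- d[j] < tads[[j]]$major_axis / 2
  }
  out
}

#' Normalized barycenter distance of a focus/TAD pair
#'
#' The focus-to-TAD barycenter separation divided by a TAD size measure:
#' half the TAD major axis (the sampling radius R of the analytic random
#' null) or the TAD radius of gyration. The convention used is recorded in
#' the result so conventions are never silently mixed.
#'
#' @param focus,tad `"storm_cluster"` objects.
#' @param convention `"half_major_axis"` (default) or `"rg"`.
#' @param dims `"2d"` or `"3d"`.
#' @return list: `value` (dimensionless), `raw_nm`, `normalizer_nm`,
#'   `convention`.
#' @export
barycenter_distance <- function(focus, tad,
                                convention = c("half_major_axis", "rg"),
                                dims = "2d") {
  convention <- match.arg(convention)
  nd <- if (dims == "3d") 3 else 2
  raw <- sqrt(sum((focus$barycenter[seq_len(nd)] - tad$barycenter[seq_len(nd)]) ^ 2))
  norm <- if (convention == "half_major_axis") tad$major_axis / 2 else tad$rg
  if (!is.finite(norm) || norm <= 0)
    stop("degenerate TAD: normalizer (", convention, ") is zero")
  list(value = raw / norm, raw_nm = raw, normalizer_nm = norm,
       convention = convention)
}

# closed forms for the expected normalized barycenter distance of points
# placed uniformly at random, normalizer = sampling radius R; rg ratios
# convert to the Rg normalizer of the matching dimensionality
.null_analytic <- list(
  "uniform_ball_projected.mean"  = 3 * pi / 16,
  "uniform_ball_3d.mean"         = 3 / 4,
  "uniform_ball_3d.median"       = 0.5 ^ (1 / 3),
  "uniform_disk.mean"            = 2 / 3,
  "uniform_disk.median"          = sqrt(0.5)
)
.null_rg_ratio <- c(uniform_ball_projected = sqrt(2 / 5),
                    uniform_ball_3d = sqrt(3 / 5),
                    uniform_disk = sqrt(1 / 2))

#' Expected barycenter distance under random placement
#'
#' The random null: foci placed uniformly at random in the domain. Closed
#' forms (normalizer = sampling radius R) exist for the mean in-plane
#' distance of points in a ball (3*pi/16 ~ 0.589 — the value the analytic
#' polar integral gives), the 3D ball mean (3/4) and median (0.5^(1/3)),
#' and the disk mean (2/3) and median (sqrt(0.5) ~ 0.707). Other
#' combinations fall back to Monte Carlo, which is also available as an
#' independent check of every closed form. With `normalizer = "rg"` the
#' value is rescaled by R/Rg of the geometry (projected ball sqrt(5/2),
#' ball sqrt(5/3), disk sqrt(2)).
#'
#' @param geometry `"uniform_ball_projected"` (uniform in a 3D ball,
#'   distance measured in the xy projection), `"uniform_ball_3d"`, or
#'   `"uniform_disk"`.
#' @param statistic `"mean"` or `"median"`.
#' @param normalizer `"R"` (sampling radius, default) or `"rg"`.
#' @param method `"analytic"` (error when no closed form exists) or
#'   `"monte_carlo"`.
#' @param n_draws Monte Carlo draws.
#' @param seed Monte Carlo seed.
#' @return list: `value`, `se` (`NA` for analytic), `method`, `geometry`,
#'   `statistic`, `normalizer`, `n_draws`, `seed`.
#' @export
null_distance <- function(geometry = c("uniform_ball_projected",
                                       "uniform_ball_3d", "uniform_disk"),
                          statistic = c("mean", "median"),
                          normalizer = c("R", "rg"),
                          method = c("analytic", "monte_carlo"),
                          n_draws = 1e6, seed = 1L) {
  geometry <- match.arg(geometry); statistic <- match.arg(statistic)
  normalizer <- match.arg(normalizer); method <- match.arg(method)
  rg_scale <- if (normalizer == "rg") 1 / .null_rg_ratio[[geometry]] else 1
  if (method == "analytic") {
    key <- paste(geometry, statistic, sep = ".")
    if (is.null(.null_analytic[[key]]))
      stop("no closed form for ", key, "; use method = 'monte_carlo'")
    value <- .null_analytic[[key]] * rg_scale
    se <- NA_real_
  } else {
    set.seed(seed)
    r <- switch(geometry,
      uniform_disk = sqrt(runif(n_draws)),
      uniform_ball_3d = runif(n_draws) ^ (1 / 3),
      uniform_ball_projected = {
        u <- matrix(rnorm(3 * n_draws), ncol = 3)
        u <- u / sqrt(rowSums(u ^ 2))
        rr <- runif(n_draws) ^ (1 / 3)
        rr * sqrt(u[, 1] ^ 2 + u[, 2] ^ 2)
      })
    if (statistic == "mean") {
      value <- mean(r) * rg_scale
      se <- sd(r) / sqrt(n_draws) * rg_scale
    } else {
      value <- median(r) * rg_scale
      hw <- 1.96 / (2 * sqrt(n_draws))   # binomial CI on the median, order-statistic form
      se <- diff(quantile(r, 0.5 + c(-hw, hw), names = FALSE)) / (2 * 1.96) * rg_scale
    }
  }
  list(value = unname(value), se = unname(se), method = method,
       geometry = geometry, statistic = statistic, normalizer = normalizer,
       n_draws = if (method == "monte_carlo") n_draws else NA, seed = seed)
}

#' Radial density distribution (RDD) of a focus within its TAD
#'
#' The central tendency (median by convention; mean also supported) of the
#' radial distances of the focus localizations from the TAD barycenter,
#' normalized by the TAD radius of gyration (or half major axis). Under
#' isotropy the radial distances are a complete summary of the radial
#' density profile, and a larger RDD means a more peripheral distribution.
#'
#' @param focus_members localization table of the focus detections.
#' @param tad a `"storm_cluster"` for the TAD.
#' @param tendency `"median"` (default) or `"mean"`.
#' @param normalizer `"rg"` (default) or `"half_major_axis"`.
#' @param dims `"2d"` or `"3d"`.
#' @return list: `value`, `tendency`, `normalizer`, `n`.
#' @export
rdd <- function(focus_members, tad, tendency = c("median", "mean"),
                normalizer = c("rg", "half_major_axis"), dims = "2d") {
  tendency <- match.arg(tendency); normalizer <- match.arg(normalizer)
  P <- .coord_matrix(focus_members, dims)
  if (!nrow(P)) stop("focus has no localizations")
  nd <- ncol(P)
  r <- sqrt(rowSums(sweep(P, 2, tad$barycenter[seq_len(nd)]) ^ 2))
  norm <- if (normalizer == "rg") tad$rg else tad$major_axis / 2
  if (!is.finite(norm) || norm <= 0) stop("degenerate TAD: zero normalizer")
  value <- if (tendency == "median") median(r) / norm else mean(r) / norm
  list(value = value, tendency = tendency, normalizer = normalizer, n = nrow(P))
}

#' Subsampling robustness of cluster statistics
#'
#' How stable are Rg and the barycenter when only a fraction of the
#' localizations is kept? For each fraction, `reps` independent uniform
#' subsamples without replacement are drawn and the statistics tabulated —
#' the check that a sparser labeling chemistry (fewer detections per
#' domain) would have produced the same cluster metrics.
#'
#' @param members localization table of one cluster.
#' @param fractions subsampling fractions in (0, 1].
#' @param reps subsamples per fraction (default 30).
#' @param seed integer seed.
#' @param dims `"2d"` or `"3d"`.
#' @return data frame with one row per fraction: `fraction`, `n_sub`,
#'   `rg_mean`, `rg_sd`, `bx_mean`, `bx_sd`, `by_mean`, `by_sd`; the
#'   full-data Rg and barycenter are attached as attributes `full_rg`,
#'   `full_barycenter`.
#' @export
subsample_robustness <- function(members, fractions = c(0.5, 0.25),
                                 reps = 30, seed = 1L, dims = "2d") {
  stopifnot(all(fractions > 0), all(fractions <= 1), reps >= 1)
  P <- .coord_matrix(members, dims)
  n <- nrow(P)
  set.seed(seed)
  rows <- lapply(fractions, function(f) {
    m <- round(f * n)
    if (m < 2) stop("fraction ", f, " leaves fewer than 2 localizations")
    rg <- numeric(reps); bx <- numeric(reps); by <- numeric(reps)
    for (k in seq_len(reps)) {
      idx <- if (m == n) seq_len(n) else sample.int(n, m)
      Q <- P[idx, , drop = FALSE]
      ctr <- colMeans(Q)
      rg[k] <- sqrt(mean(rowSums(sweep(Q, 2, ctr) ^ 2)))
      bx[k] <- ctr[1]; by[k] <- ctr[2]
    }
    data.frame(fraction = f, n_sub = m, rg_mean = mean(rg), rg_sd = sd(rg),
               bx_mean = mean(bx), bx_sd = sd(bx),
               by_mean = mean(by), by_sd = sd(by))
  })
  out <- do.call(rbind, rows)
  ctr <- colMeans(P)
  attr(out, "full_rg") <- sqrt(mean(rowSums(sweep(P, 2, ctr) ^ 2)))
  attr(out, "full_barycenter") <- ctr
  out
}
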