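#' Significance tier from a P value
#'
#' The tiered reporting convention used throughout:
#' `****` P < 0.0001, `***` P < 0.0005, `**` P < 0.01, `*` P < 0.05,
#' otherwise `N.S.` (note the nonstandard 0.0005 third tier).
#'
#' @param p P value(s) in `[0, 1]`.
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 1e-4, "****",
    ifelse(p < 5e-4, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "N.S."))))
}

#' Unpaired two-sample t test with tiered reporting
#'
#' Student (pooled-variance, default) or Welch variant, two-sided, with the
#' significance tier attached. No multiple-testing correction is applied;
#' tiers summarize raw P values.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param variant `"student"` or `"welch"`.
#' @return list of class `"tier_test"`: `n`, `means`, `sds`, `t`, `df`,
#'   `p`, `tier`, `variant`.
#' @export
t_test_tiered <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (var(a) == 0 && var(b) == 0)
    stop("zero variance in both groups: t statistic undefined")
  ht <- t.test(a, b, var.equal = (variant == "student"))
  structure(list(n = c(length(a), length(b)),
                 means = c(mean(a), mean(b)), sds = c(sd(a), sd(b)),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, tier = significance_tier(ht$p.value),
                 variant = variant),
            class = "tier_test")
}

#' @export
print.tier_test <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4f, df = %.2f, P = %.3g  [%s]\n",
              x$variant, x$t, x$df, x$p, x$tier))
  cat(sprintf("  group means %.4g vs %.4g (sd %.3g / %.3g, n %d / %d)\n",
              x$means[1], x$means[2], x$sds[1], x$sds[2], x$n[1], x$n[2]))
  invisible(x)
}

#' Group summaries in scatter and box conventions
#'
#' For each group: mean +/- sd (scatter convention) and median, quartiles
#' and whiskers (box convention, whiskers at the most extreme observations
#' within 1.5x the interquartile range of the box limits). Empty groups
#' are dropped with a warning.
#'
#' @param values numeric vector.
#' @param group grouping vector of the same length.
#' @return data frame, one row per group: `group`, `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
summarize_groups <- function(values, group) {
  stopifnot(length(values) == length(group))
  levs <- unique(group)
  rows <- lapply(levs, function(g) {
    v <- values[group == g & !is.na(values)]
    if (!length(v)) { warning("group '", g, "' is empty; omitted"); return(NULL) }
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- v[v >= q[1] - 1.5 * iqr]
    hi <- v[v <= q[3] + 1.5 * iqr]
    data.frame(group = as.character(g), n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0,
               median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(lo), whisker_hi = max(hi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
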