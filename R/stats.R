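# Cross-density group comparison of metric curves, plus the demographic
# worked examples (chi-squared on a sex table, one-way ANOVA rebuilt from
# printed summary statistics).

#' Default density grid
#'
#' Edge densities ("sparsity degrees") 0.10 to 0.50 in steps of 0.01;
#' 41 points.
#'
#' @return Numeric vector of length 41.
#' @export
density_grid <- function() seq(0.10, 0.50, by = 0.01)

#' Metric curves for a set of subjects
#'
#' For every subject and every density on the grid: binarize the
#' weighted connectivity matrix, then compute the four small-world
#' metrics. Returns one long data frame — the natural shape for the
#' per-density group tests.
#'
#' @param conns Named list of [connectivity_matrix()] objects (one per
#'   subject), or of square numeric matrices.
#' @param groups Character vector of group labels, one per subject
#'   (recycled names of `conns` are used as subject ids).
#' @param grid Strictly increasing density values, default
#'   [density_grid()].
#' @param quiet Suppress per-network shortfall warnings from
#'   [binarize_at_density()] (default `TRUE`; shortfalls are still
#'   visible in the `shortfall` column).
#' @return Data frame with columns `subject_id`, `group`, `density`,
#'   `cp`, `lp`, `eg`, `eloc`, `unreachable_pairs`, `shortfall`.
#' @export
build_metric_curves <- function(conns, groups, grid = density_grid(),
                                quiet = TRUE) {
  if (length(conns) != length(groups))
    stopf("got %d connectivity matrices but %d group labels",
          length(conns), length(groups))
  if (is.unsorted(grid, strictly = TRUE))
    stopf("the density grid must be strictly increasing")
  ids <- names(conns)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_along(conns))
  rows <- vector("list", length(conns) * length(grid))
  k <- 0L
  for (s in seq_along(conns)) {
    for (d in grid) {
      net <- tryCatch({
        if (quiet) suppressWarnings(binarize_at_density(conns[[s]], d))
        else binarize_at_density(conns[[s]], d)
      }, error = function(e)
        stopf("subject %s, density %.2f: %s", ids[s], d, conditionMessage(e)))
      ms <- tryCatch(metric_set(net), error = function(e)
        stopf("subject %s, density %.2f: %s", ids[s], d, conditionMessage(e)))
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = ids[s], group = groups[s], density = d,
        cp = ms$cp, lp = ms$lp, eg = ms$eg, eloc = ms$eloc,
        unreachable_pairs = ms$unreachable_pairs,
        shortfall = attr(net, "shortfall"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pooled-variance two-sample t test
#'
#' Student's two-tailed t test with the pooled variance estimate. If the
#' pooled variance is zero the test degenerates: equal means give
#' `t = 0, p = 1`; unequal means with zero variance are an error.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return List with elements `t`, `p`, `df`.
#' @export
two_sample_ttest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("each sample needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = df))
    stopf("zero pooled variance with unequal means: t is undefined")
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)`. The family size is explicit because the curves are
#' tested once per density: the default family is the 41 densities
#' within one metric (`m = length(raw_ps)` when called per metric), but
#' a whole-table family can be passed instead.
#'
#' @param raw_ps Raw P values in `[0, 1]`.
#' @param m Family size (default: the number of P values given).
#' @return Adjusted P values, capped at 1.
#' @export
bonferroni_adjust <- function(raw_ps, m = length(raw_ps)) {
  if (any(raw_ps < 0 | raw_ps > 1, na.rm = TRUE))
    stopf("raw P values must lie in [0, 1]")
  if (!is_count(m)) stopf("family size m must be a positive integer")
  pmin(1, raw_ps * m)
}

#' Per-density, per-metric comparison of two groups
#'
#' For each density on the grid and each of the four metrics, runs the
#' pooled two-sample t test between the two groups' subjects and
#' attaches raw and Bonferroni-adjusted P values. The correction family
#' defaults to the densities within one metric (`per_metric`); `table`
#' corrects over all densities x metrics at once.
#'
#' @param curves Data frame from [build_metric_curves()].
#' @param group_a,group_b Group labels to contrast (t is signed
#'   `a - b`).
#' @param alpha Significance level applied to the adjusted P.
#' @param family `"per_metric"` or `"table"`.
#' @return Data frame of class `comparison_table` with columns
#'   `density`, `metric`, `t`, `p_raw`, `p_adj`, `significant`.
#' @export
compare_groups <- function(curves, group_a, group_b, alpha = 0.05,
                           family = c("per_metric", "table")) {
  family <- match.arg(family)
  metrics <- c("cp", "lp", "eg", "eloc")
  for (g in c(group_a, group_b))
    if (!g %in% curves$group) stopf("group '%s' not present in the curves", g)
  grid <- sort(unique(curves$density))
  out <- expand.grid(density = grid, metric = metrics,
                     stringsAsFactors = FALSE)
  res <- mapply(function(d, met) {
    rows <- curves$density == d
    a <- curves[rows & curves$group == group_a, met]
    b <- curves[rows & curves$group == group_b, met]
    tt <- tryCatch(two_sample_ttest(a, b), error = function(e)
      stopf("density %.2f, metric %s: %s", d, met, conditionMessage(e)))
    c(tt$t, tt$p)
  }, out$density, out$metric)
  out$t <- res[1, ]
  out$p_raw <- res[2, ]
  m <- if (family == "per_metric") length(grid) else length(grid) * length(metrics)
  out$p_adj <- bonferroni_adjust(out$p_raw, m = m)
  out$significant <- out$p_adj < alpha
  attr(out, "groups") <- c(group_a, group_b)
  attr(out, "alpha") <- alpha
  attr(out, "family") <- family
  attr(out, "test") <- "two-sample two-tailed t (pooled variance)"
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Wide (one density per row) view of a comparison table
#'
#' Reshapes the long comparison table into the conventional report
#' layout: one density per row, one column per metric.
#'
#' @param tbl A [compare_groups()] result.
#' @param value Which column to spread: `"p_raw"`, `"p_adj"` or `"t"`.
#' @return Data frame with columns `density`, `cp`, `lp`, `eg`, `eloc`.
#' @export
comparison_wide <- function(tbl, value = c("p_raw", "p_adj", "t")) {
  value <- match.arg(value)
  grid <- sort(unique(tbl$density))
  out <- data.frame(density = grid)
  for (met in c("cp", "lp", "eg", "eloc")) {
    sub <- tbl[tbl$metric == met, ]
    out[[met]] <- sub[[value]][match(grid, sub$density)]
  }
  out
}

#' Cohen's d effect-size curve for one metric
#'
#' Pooled-SD standardized mean difference (`a - b`) per density;
#' companion output for comparing how strongly the two connectivity
#' methods separate the same groups.
#'
#' @inheritParams compare_groups
#' @param metric One of `"cp"`, `"lp"`, `"eg"`, `"eloc"`.
#' @return Data frame with columns `density`, `d`.
#' @export
effect_size_curve <- function(curves, group_a, group_b, metric = "cp") {
  metric <- match.arg(metric, c("cp", "lp", "eg", "eloc"))
  grid <- sort(unique(curves$density))
  d <- vapply(grid, function(dd) {
    rows <- curves$density == dd
    a <- curves[rows & curves$group == group_a, metric]
    b <- curves[rows & curves$group == group_b, metric]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  }, numeric(1))
  data.frame(density = grid, d = d)
}

#' Pearson chi-squared test of independence
#'
#' Without continuity correction; `df = (rows - 1)(cols - 1)`. Used for
#' contingency tables such as sex-by-group counts.
#'
#' @param counts Matrix of non-negative counts with at least two nonzero
#'   rows and columns.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("zero row or column marginal: the test is undefined")
  if (sum(rowSums(counts) > 0) < 2 || sum(colSums(counts) > 0) < 2)
    stopf("need at least two nonzero rows and columns")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the between/within sums of squares from per-group means,
#' standard deviations and sizes — the situation when only a published
#' summary table is available. `F` has `(k - 1, N - k)` degrees of
#' freedom. Note that an F recomputed from rounded summaries can differ
#' from one computed on the raw data.
#'
#' @param means,sds,ns Numeric vectors of per-group means, standard
#'   deviations (`> 0`) and sizes (`>= 2`), equal length `k >= 2`.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k)
    stopf("means, sds, ns must have equal length >= 2")
  if (any(ns < 2)) stopf("every group needs n >= 2")
  if (any(sds <= 0)) stopf("standard deviations must be > 0")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}
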