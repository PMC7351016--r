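# Synthetic multi-subject ROI time-series cohorts.
#
# The generator stands in for resting-state fMRI at the region level: each
# subject is a T x M matrix of regional mean signals with a modular spatial
# correlation structure, lag-1 temporal autocorrelation, and an optional
# shared global signal. Group membership perturbs the within-module
# correlation, which is the effect the downstream pipeline is asked to
# detect.

#' Specification of a synthetic ROI time-series cohort
#'
#' Collects every parameter of the cohort generator in one validated
#' object. The defaults emulate a three-group study design (healthy
#' controls, mild cognitive impairment, Alzheimer's disease) with 90
#' regions, 155 volumes at a repetition time of 2 s.
#'
#' @param n_per_group Named integer vector of subjects per group.
#' @param n_regions Number of regions M.
#' @param n_timepoints Number of time points T per subject.
#' @param tr Repetition time in seconds (sampling interval of the series).
#' @param module_partition Integer vector of length `n_regions` assigning
#'   each region to a module; defaults to six contiguous, near-equal
#'   modules.
#' @param r_within Target correlation between regions in the same module
#'   for the reference (first) group, in `[0, 1]`.
#' @param r_between Target correlation between regions in different
#'   modules, `0 <= r_between <= r_within`.
#' @param group_deltas Named numeric vector (same names as `n_per_group`)
#'   added to `r_within` per group; models degraded or enhanced local
#'   (within-module) connectivity.
#' @param ar_coef Lag-1 autoregressive coefficient in `[0, 1)` applied to
#'   every regional series.
#' @param global_amp Standard-deviation ratio of a shared global signal
#'   added to all regions (`>= 0`); `0.2` injects the mild common variance
#'   typical of region-level resting-state data after preprocessing.
#' @param seed Master integer seed; all per-subject seeds derive from it.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [make_module_covariance()]
#' @export
cohort_spec <- function(n_per_group = c(hc = 27, mci = 33, ad = 24),
                        n_regions = 90,
                        n_timepoints = 155,
                        tr = 2.0,
                        module_partition = default_partition(n_regions),
                        r_within = 0.5,
                        r_between = 0.1,
                        group_deltas = NULL,
                        ar_coef = 0.3,
                        global_amp = 0.2,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || anyDuplicated(names(n_per_group)))
    stopf("n_per_group must have unique group names")
  if (any(n_per_group < 0) || any(n_per_group != round(n_per_group)))
    stopf("n_per_group must be non-negative integers")
  if (!is_count(n_regions)) stopf("n_regions must be a positive integer")
  if (!is_count(n_timepoints) || n_timepoints < 4)
    stopf("n_timepoints must be an integer >= 4 (nuisance covariates are regressed out later)")
  if (!is_number(tr) || tr <= 0) stopf("tr must be a positive number of seconds")
  if (length(module_partition) != n_regions)
    stopf("module_partition must assign all %d regions (got length %d)",
          n_regions, length(module_partition))
  if (anyNA(module_partition)) stopf("module_partition contains missing assignments")
  if (!is_number(r_within) || r_within < 0 || r_within > 1)
    stopf("r_within must lie in [0, 1], got %g", r_within)
  if (!is_number(r_between) || r_between < 0 || r_between > r_within)
    stopf("r_between must satisfy 0 <= r_between <= r_within, got %g", r_between)
  if (is.null(group_deltas)) {
    group_deltas <- stats::setNames(numeric(length(n_per_group)), names(n_per_group))
    # default study-like effects: first group is reference; a mild increase
    # for an intermediate group and a deficit for the last mimic the
    # compensatory-then-degraded pattern reported for MCI and AD
    if (length(group_deltas) == 3L) group_deltas[] <- c(0, 0.05, -0.15)
  }
  if (!all(names(n_per_group) %in% names(group_deltas)))
    stopf("group_deltas must cover every group in n_per_group")
  group_deltas <- group_deltas[names(n_per_group)]
  for (g in names(n_per_group)) {
    rw <- r_within + group_deltas[[g]]
    if (rw < 0 || rw >= 1)
      stopf("group '%s': r_within + delta = %g is outside [0, 1)", g, rw)
  }
  if (!is_number(ar_coef) || ar_coef < 0 || ar_coef >= 1)
    stopf("ar_coef must lie in [0, 1), got %g (>= 1 is non-stationary)", ar_coef)
  if (!is_number(global_amp) || global_amp < 0)
    stopf("global_amp must be >= 0, got %g", global_amp)
  structure(
    list(n_per_group = n_per_group, n_regions = n_regions,
         n_timepoints = n_timepoints, tr = tr,
         module_partition = as.integer(module_partition),
         r_within = r_within, r_between = r_between,
         group_deltas = group_deltas, ar_coef = ar_coef,
         global_amp = global_amp, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default contiguous module partition
#'
#' Splits `n_regions` regions into `k` contiguous modules of near-equal
#' size (a coarse stand-in for large-scale functional systems).
#'
#' @param n_regions Number of regions.
#' @param k Number of modules.
#' @return Integer vector of module labels, length `n_regions`.
#' @export
default_partition <- function(n_regions, k = 6) {
  sort(rep_len(seq_len(k), n_regions))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects (%s), M = %d regions, T = %d, TR = %gs\n",
              sum(x$n_per_group),
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = ", "),
              x$n_regions, x$n_timepoints, x$tr))
  cat(sprintf("  r_within = %g, r_between = %g, deltas = [%s]\n",
              x$r_within, x$r_between,
              paste(sprintf("%s=%+g", names(x$group_deltas), x$group_deltas), collapse = ", ")))
  cat(sprintf("  ar_coef = %g, global_amp = %g, %d modules, seed = %d\n",
              x$ar_coef, x$global_amp, length(unique(x$module_partition)), x$seed))
  invisible(x)
}

#' One subject's regional time series
#'
#' Light container for a T x M matrix of regional mean signals.
#'
#' @param values Numeric T x M matrix (rows = time points, columns = regions).
#' @param subject_id Subject label.
#' @param group Group label.
#' @param tr Repetition time in seconds.
#' @return An object of class `ts_matrix`.
#' @export
ts_matrix <- function(values, subject_id = "s1", group = NA_character_, tr = 2.0) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (anyNA(values)) stopf("time series contain missing values")
  structure(list(values = values, subject_id = subject_id,
                 group = group, tr = tr),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> subject '%s' (group %s): T = %d, M = %d, TR = %gs\n",
              x$subject_id, x$group, nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Block (modular) correlation matrix
#'
#' Builds the M x M spatial correlation matrix used by the cohort
#' generator: unit diagonal, `r_within` inside each module block and
#' `r_between` elsewhere. If the construction is not positive
#' semidefinite (possible for extreme parameter combinations), negative
#' eigenvalues are clipped to zero and the diagonal renormalized to 1,
#' with a warning.
#'
#' @inheritParams cohort_spec
#' @return Symmetric M x M correlation matrix.
#' @export
make_module_covariance <- function(n_regions, module_partition,
                                   r_within, r_between) {
  if (!is_count(n_regions)) stopf("n_regions must be a positive integer")
  if (length(module_partition) != n_regions)
    stopf("module_partition must assign all %d regions (got length %d)",
          n_regions, length(module_partition))
  if (!is_number(r_within) || r_within < 0 || r_within > 1)
    stopf("r_within must lie in [0, 1], got %g", r_within)
  if (!is_number(r_between) || r_between < 0 || r_between > 1)
    stopf("r_between must lie in [0, 1], got %g", r_between)
  same <- outer(module_partition, module_partition, "==")
  S <- ifelse(same, r_within, r_between)
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    warnf("module covariance is not positive semidefinite (min eigenvalue %.3g); clipping negative eigenvalues and renormalizing the diagonal",
          min(ev$values))
    vals <- pmax(ev$values, 0)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(S))
    d[d == 0] <- 1
    S <- S / tcrossprod(d)
    S <- (S + t(S)) / 2
  }
  S
}

#' Simulate one subject's regional time series
#'
#' Draws T correlated Gaussian innovation vectors with the given spatial
#' covariance, passes each regional series through a lag-1 autoregressive
#' filter (innovations rescaled so the stationary marginal variance stays
#' at the covariance diagonal), and finally adds `global_amp` times a
#' shared standard-normal time course to every region. Identical seeds
#' give bit-identical output.
#'
#' @param covariance Positive-semidefinite M x M spatial covariance.
#' @param n_timepoints Number of time points T.
#' @param ar_coef Lag-1 autoregressive coefficient in `[0, 1)`.
#' @param global_amp Standard-deviation ratio of the shared global signal.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param subject_id,group,tr Metadata stored on the result.
#' @return A [ts_matrix()].
#' @export
simulate_subject <- function(covariance, n_timepoints,
                             ar_coef = 0, global_amp = 0, seed = NULL,
                             subject_id = "s1", group = NA_character_,
                             tr = 2.0) {
  if (!is.matrix(covariance) || nrow(covariance) != ncol(covariance))
    stopf("covariance must be a square matrix")
  if (!is_number(ar_coef) || ar_coef < 0 || ar_coef >= 1)
    stopf("ar_coef must lie in [0, 1), got %g (>= 1 is non-stationary)", ar_coef)
  if (!is_number(global_amp) || global_amp < 0)
    stopf("global_amp must be >= 0")
  m <- ncol(covariance)
  burn <- if (ar_coef > 0) 50L else 0L
  n_total <- n_timepoints + burn
  x <- with_seed(seed, {
    innov <- MASS::mvrnorm(n_total, mu = rep(0, m), Sigma = covariance)
    innov <- matrix(innov, nrow = n_total, ncol = m)
    if (ar_coef > 0) {
      # scale innovations so the stationary AR(1) variance equals Sigma_ii
      innov <- innov * sqrt(1 - ar_coef^2)
      innov <- apply(innov, 2, function(e)
        as.numeric(stats::filter(e, ar_coef, method = "recursive")))
      innov <- innov[(burn + 1):n_total, , drop = FALSE]
    }
    if (global_amp > 0) {
      g <- stats::rnorm(n_timepoints)
      innov <- innov + global_amp * g
    }
    innov
  })
  colnames(x) <- sprintf("R%03d", seq_len(m))
  ts_matrix(x, subject_id = subject_id, group = group, tr = tr)
}

#' Generate a full synthetic cohort
#'
#' One [ts_matrix()] per subject. Group `g` uses within-module correlation
#' `r_within + group_deltas[g]`. Per-subject seeds are derived
#' deterministically from `spec$seed`, so the cohort is a pure function of
#' its spec and subjects can be regenerated independently.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `roi_cohort`: a list with `subjects` (list
#'   of `ts_matrix`), `manifest` (data frame of subject_id, group, seed)
#'   and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  groups <- names(spec$n_per_group)
  covs <- lapply(groups, function(g) {
    make_module_covariance(spec$n_regions, spec$module_partition,
                           spec$r_within + spec$group_deltas[[g]],
                           spec$r_between)
  })
  names(covs) <- groups
  n_total <- sum(spec$n_per_group)
  manifest <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n_total)),
    group = rep(groups, times = spec$n_per_group),
    seed = vapply(seq_len(n_total), function(i) derive_seed(spec$seed, i),
                  integer(1)),
    stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(n_total), function(i) {
    simulate_subject(covs[[manifest$group[i]]], spec$n_timepoints,
                     ar_coef = spec$ar_coef, global_amp = spec$global_amp,
                     seed = manifest$seed[i],
                     subject_id = manifest$subject_id[i],
                     group = manifest$group[i], tr = spec$tr)
  })
  names(subjects) <- manifest$subject_id
  structure(list(subjects = subjects, manifest = manifest, spec = spec),
            class = "roi_cohort")
}

#' @export
print.roi_cohort <- function(x, ...) {
  cat(sprintf("<roi_cohort> %d subjects, M = %d, T = %d\n",
              length(x$subjects), x$spec$n_regions, x$spec$n_timepoints))
  print(table(x$manifest$group))
  invisible(x)
}

#' Write a cohort to a directory of TSV files
#'
#' One `<subject_id>.tsv` per subject (T rows x M columns, no header),
#' plus `manifest.tsv` (subject_id, group, seed) and the JSON-serialized
#' spec.
#'
#' @param cohort A `roi_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "roi_cohort")) stopf("cohort must be a roi_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in cohort$subjects) {
    f <- file.path(dir, paste0(s$subject_id, ".tsv"))
    write_matrix(s$values, f)
    files <- c(files, f)
  }
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(cohort$manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sf <- file.path(dir, "cohort_spec.json")
  spec <- cohort$spec
  jsonlite::write_json(unclass(spec), sf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf, sf))
}
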