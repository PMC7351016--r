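# Delimited-text matrix I/O and end-to-end pipeline orchestration.
# Everything is plain TSV + JSON so runs are diff-able and reproducible
# byte for byte from a config and a seed.

#' Write a numeric matrix as TSV
#'
#' Tab-separated, no header, 15 significant digits, so a round trip
#' through [read_matrix()] preserves values to at least 12 significant
#' digits.
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || !is.numeric(m)) stopf("m must be a numeric matrix")
  lines <- apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV numeric matrix
#'
#' Rejects ragged rows and non-numeric cells, naming the first offending
#' line.
#'
#' @param path Input file.
#' @param expect_symmetric If `TRUE`, additionally validate symmetry (to
#'   1e-12 relative) for a square matrix.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path, expect_symmetric = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("%s: no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stopf("%s: ragged row at line %d (%d fields, expected %d)",
          path, bad, ncols[bad], ncols[1])
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stopf("%s: non-numeric cell at line %d", path, bad[1])
  m <- do.call(rbind, vals)
  if (expect_symmetric) {
    if (nrow(m) != ncol(m)) stopf("%s: expected a square matrix", path)
    if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
      stopf("%s: matrix is not symmetric", path)
  }
  m
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration for [run_pipeline()].
#'
#' @param cohort A [cohort_spec()].
#' @param prep A [prep_config()] or `NULL` to skip temporal
#'   preprocessing.
#' @param lasso A [lasso_config()].
#' @param grid Density grid, default [density_grid()].
#' @param null_cfg A [null_config()] (reserved for small-world
#'   summaries).
#' @param contrasts List of length-2 character vectors of group labels
#'   to compare; defaults to every group against the first (reference)
#'   group.
#' @param methods Connectivity methods to run: `"pearson"`, `"l1"` or
#'   both.
#' @param output_dir Directory the run writes into.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            prep = prep_config(tr = cohort$tr),
                            lasso = lasso_config(),
                            grid = density_grid(),
                            null_cfg = null_config(),
                            contrasts = NULL,
                            methods = c("pearson", "l1"),
                            output_dir = tempfile("roinet_run_")) {
  methods <- match.arg(methods, several.ok = TRUE)
  groups <- names(cohort$n_per_group)
  if (is.null(contrasts))
    contrasts <- lapply(setdiff(groups, groups[1]), function(g) c(g, groups[1]))
  for (ct in contrasts) {
    if (length(ct) != 2) stopf("each contrast must name exactly two groups")
    missing <- setdiff(ct, groups)
    if (length(missing))
      stopf("contrast references unknown group(s): %s",
            paste(missing, collapse = ", "))
  }
  structure(list(cohort = cohort, prep = prep, lasso = lasso, grid = grid,
                 null_cfg = null_cfg, contrasts = contrasts,
                 methods = methods, output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> connectivity (each requested method) ->
#' metric curves -> group comparisons, writing every intermediate as TSV
#' under `cfg$output_dir` along with a manifest of MD5 content hashes.
#' Re-running the same config reproduces every file byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest data frame (`stage`, `file`, `md5`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stopf("cfg must be a pipeline_config")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  record <- function(stage, files) data.frame(
    stage = stage, file = basename(files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  manifest <- list()

  cohort <- generate_cohort(cfg$cohort)
  ts_dir <- file.path(cfg$output_dir, "timeseries")
  manifest$simulate <- record("simulate", write_cohort(cohort, ts_dir))

  subjects <- cohort$subjects
  if (!is.null(cfg$prep)) {
    subjects <- lapply(subjects, prep_subject, cfg = cfg$prep)
    prep_dir <- file.path(cfg$output_dir, "prep")
    dir.create(prep_dir, showWarnings = FALSE)
    pf <- vapply(subjects, function(s) {
      f <- file.path(prep_dir, paste0(s$subject_id, ".tsv"))
      write_matrix(s$values, f)
      f
    }, character(1))
    manifest$prep <- record("prep", pf)
  }

  curves_by_method <- list()
  for (method in cfg$methods) {
    conns <- lapply(subjects, function(s) {
      if (method == "pearson") pearson_connectivity(s)
      else l1_connectivity(s, cfg$lasso)
    })
    conn_dir <- file.path(cfg$output_dir, paste0("connectivity_", method))
    dir.create(conn_dir, showWarnings = FALSE)
    cf <- vapply(names(conns), function(id) {
      f <- file.path(conn_dir, paste0(id, ".tsv"))
      write_matrix(conns[[id]]$weights, f)
      f
    }, character(1))
    side <- file.path(conn_dir, "method.json")
    jsonlite::write_json(
      list(method = method,
           lambda_used = if (method == "l1")
             vapply(conns, function(x) x$lambda_used, numeric(1)) else NULL,
           symmetrization = if (method == "l1") cfg$lasso$symmetrization else NULL),
      side, auto_unbox = TRUE, digits = NA)
    manifest[[paste0("connect_", method)]] <-
      record(paste0("connect_", method), c(cf, side))

    curves <- build_metric_curves(conns, cohort$manifest$group, grid = cfg$grid)
    curves_f <- file.path(cfg$output_dir,
                          sprintf("metric_curves_%s.tsv", method))
    utils::write.table(curves, curves_f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest[[paste0("metrics_", method)]] <-
      record(paste0("metrics_", method), curves_f)
    curves_by_method[[method]] <- curves

    for (ct in cfg$contrasts) {
      tbl <- compare_groups(curves, ct[1], ct[2])
      f <- file.path(cfg$output_dir,
                     sprintf("compare_%s_%s_vs_%s.tsv", method, ct[1], ct[2]))
      utils::write.table(as.data.frame(tbl), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest[[paste(method, ct[1], ct[2], sep = "_")]] <-
        record(paste0("compare_", method), f)
    }
  }

  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  mf <- file.path(cfg$output_dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
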