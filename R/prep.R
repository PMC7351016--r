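# Temporal preprocessing of ROI time series: nuisance regression followed
# by zero-phase band-pass filtering.

#' Preprocessing configuration
#'
#' @param band_low,band_high Pass-band edges in Hz; must satisfy
#'   `0 < band_low < band_high < 1/(2 tr)` (the Nyquist frequency). The
#'   defaults bracket the 0.03-0.06 Hz band in which resting-state
#'   small-world topology is most prominent.
#' @param tr Repetition time (sampling interval) in seconds.
#' @param detrend If `TRUE`, an intercept and a linear trend are included
#'   among the nuisance regressors.
#' @param filter_order Butterworth filter order (applied forward and
#'   backward, so the effective attenuation order doubles and the phase
#'   response is zero).
#' @param extra_covariates Optional T x q matrix of additional nuisance
#'   regressors (e.g. motion parameters or tissue signals).
#' @return An object of class `prep_config`.
#' @export
prep_config <- function(band_low = 0.03, band_high = 0.06, tr = 2.0,
                        detrend = TRUE, filter_order = 4,
                        extra_covariates = NULL) {
  nyquist <- 1 / (2 * tr)
  if (!is_number(band_low) || !is_number(band_high) ||
      band_low <= 0 || band_low >= band_high || band_high >= nyquist)
    stopf("pass band must satisfy 0 < band_low < band_high < %g Hz (Nyquist for TR = %g s); got [%g, %g]",
          nyquist, tr, band_low, band_high)
  if (!is_count(filter_order)) stopf("filter_order must be a positive integer")
  if (!is.null(extra_covariates) && !is.matrix(extra_covariates))
    stopf("extra_covariates must be NULL or a T x q matrix")
  structure(list(band_low = band_low, band_high = band_high, tr = tr,
                 detrend = isTRUE(detrend), filter_order = filter_order,
                 extra_covariates = extra_covariates),
            class = "prep_config")
}

#' Build the default nuisance design matrix
#'
#' Intercept, optional linear trend, and any extra covariates, column-named
#' for error reporting.
#'
#' @param n_timepoints Number of time points T.
#' @param detrend Include a linear trend column?
#' @param extra_covariates Optional T x q matrix appended to the design.
#' @return T x q numeric design matrix.
#' @export
nuisance_design <- function(n_timepoints, detrend = TRUE,
                            extra_covariates = NULL) {
  X <- cbind(intercept = rep(1, n_timepoints))
  if (detrend) X <- cbind(X, trend = seq_len(n_timepoints))
  if (!is.null(extra_covariates)) {
    ec <- as.matrix(extra_covariates)
    if (nrow(ec) != n_timepoints)
      stopf("extra_covariates has %d rows but T = %d", nrow(ec), n_timepoints)
    if (is.null(colnames(ec))) colnames(ec) <- sprintf("cov%d", seq_len(ncol(ec)))
    X <- cbind(X, ec)
  }
  X
}

#' Regress nuisance covariates out of every regional series
#'
#' Ordinary least-squares residuals per region; by construction the
#' residuals are orthogonal to every covariate column. The covariate
#' matrix must have full column rank; offending (linearly dependent)
#' columns are named in the error.
#'
#' @param ts A [ts_matrix()] or numeric T x M matrix.
#' @param covariates T x q numeric matrix of nuisance regressors
#'   (typically including an intercept and a linear trend; see
#'   [nuisance_design()]).
#' @return Object of the same type as `ts`, containing residuals.
#' @export
nuisance_regress <- function(ts, covariates) {
  V <- ts_values(ts)
  X <- as.matrix(covariates)
  if (nrow(X) != nrow(V))
    stopf("covariates have %d rows but the series has T = %d", nrow(X), nrow(V))
  if (ncol(X) >= nrow(V))
    stopf("need q < T: %d covariates for %d time points", ncol(X), nrow(V))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    nm <- colnames(X)
    lab <- if (is.null(nm)) as.character(bad) else nm[bad]
    stopf("covariate matrix is rank deficient; dependent column(s): %s",
          paste(lab, collapse = ", "))
  }
  res <- qr.resid(qrX, V)
  if (inherits(ts, "ts_matrix")) {
    dimnames(res) <- dimnames(ts$values)
    ts$values <- res
    ts
  } else res
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass of order `cfg$filter_order`, applied forward and
#' backward ([signal::filtfilt()]) so no temporal shift is introduced.
#' Frequency content outside `[band_low, band_high]` is attenuated.
#'
#' @param ts A [ts_matrix()] or numeric T x M matrix; the repetition time
#'   is taken from `cfg$tr`.
#' @param cfg A [prep_config()].
#' @return Object of the same type as `ts`, filtered per region.
#' @export
bandpass <- function(ts, cfg = prep_config()) {
  if (!inherits(cfg, "prep_config")) stopf("cfg must be a prep_config")
  V <- ts_values(ts)
  nyquist <- 1 / (2 * cfg$tr)
  # filtfilt's edge padding needs 3 x the filter length; a band-pass of
  # order k has 2k + 1 coefficients
  min_t <- 3 * (2 * cfg$filter_order + 1)
  if (nrow(V) <= min_t)
    stopf("series too short to filter: T = %d but the order-%d band-pass needs T > %d",
          nrow(V), cfg$filter_order, min_t)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low, cfg$band_high) / nyquist,
                       type = "pass")
  out <- apply(V, 2, function(x) signal::filtfilt(bf, x))
  out <- matrix(out, nrow = nrow(V), ncol = ncol(V), dimnames = dimnames(V))
  if (inherits(ts, "ts_matrix")) {
    ts$values <- out
    ts
  } else out
}

#' Full temporal preprocessing of one subject
#'
#' Nuisance regression (intercept, optional linear trend, extra
#' covariates) followed by the zero-phase band-pass, in that order.
#'
#' @inheritParams bandpass
#' @return Preprocessed object of the same type as `ts`.
#' @export
prep_subject <- function(ts, cfg = prep_config()) {
  V <- ts_values(ts)
  X <- nuisance_design(nrow(V), detrend = cfg$detrend,
                       extra_covariates = cfg$extra_covariates)
  bandpass(nuisance_regress(ts, X), cfg)
}
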