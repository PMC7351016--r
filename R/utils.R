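# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and an index
#'
#' Deterministic, collision-resistant enough for per-subject / per-null
#' streams; stays inside the 32-bit integer range R requires.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Extract the T x M numeric matrix from a ts_matrix or plain matrix input.
ts_values <- function(ts) {
  if (inherits(ts, "ts_matrix")) return(ts$values)
  if (is.matrix(ts) && is.numeric(ts)) return(ts)
  stopf("expected a 'ts_matrix' or a numeric T x M matrix, got %s",
        paste(class(ts), collapse = "/"))
}
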