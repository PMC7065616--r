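# Internal helpers: classed conditions, seed scoping, small numerics.

cp_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "corneapuff_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cp_stop("corneapuff_invalid_spec", "'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0)
    cp_stop("corneapuff_invalid_spec", "'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0)
    cp_stop("corneapuff_invalid_spec", "'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-record seed derived from a cohort seed; kept < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587)
}

# Trapezoidal integral of y over x (either direction).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
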