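# Internal helpers shared across modules.

# Sampling interval of a uniform grid; errors if the grid is not uniform.
grid_dt <- function(time, tol = 1e-8) {
  if (length(time) < 2L) abort("need at least 2 samples to define a grid")
  dt <- diff(time)
  if (any(dt <= 0)) abort("time must be strictly increasing")
  if (diff(range(dt)) > tol * max(dt)) abort("time grid is not uniform")
  mean(dt)
}

assert_same_length <- function(...) {
  lens <- lengths(list(...))
  if (length(unique(lens)) != 1L) {
    abort(sprintf("inputs must have equal length (got %s)",
                  paste(lens, collapse = ", ")))
  }
  invisible(lens[[1L]])
}

# Effectively constant up to floating-point jitter (e.g. a filtered
# constant channel).
near_constant <- function(x, tol = 1e-10) {
  s <- sd(x)
  !is.finite(s) || s <= tol * (1 + abs(mean(x)))
}

# z-score a vector; errors on (near-)zero spread unless `centre_only`.
zscore_vec <- function(x, centre_only = FALSE) {
  if (near_constant(x)) {
    if (centre_only) return(x - mean(x))
    abort("cannot z-score a constant vector")
  }
  (x - mean(x)) / sd(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
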