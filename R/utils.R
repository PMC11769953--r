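# Internal helpers shared across modules.

# Deterministically spawn a child seed from a master seed and a stream label.
# Keeps results below .Machine$integer.max so seeds stay valid R integers.
spawn_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483562L + 1L)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_probability_matrix <- function(A, name = "transition matrix", tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort(sprintf("%s must be square", name))
  if (any(A < -tol)) abort(sprintf("%s has negative entries", name))
  if (any(abs(rowSums(A) - 1) > tol)) abort(sprintf("rows of %s must sum to 1", name))
  invisible(A)
}

assert_simplex <- function(p, name = "initial distribution", tol = 1e-8) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    abort(sprintf("%s must be a probability vector", name))
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
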