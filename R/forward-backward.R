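#' Forward-backward state posteriors for a single chain
#'
#' Exact posterior state responsibilities (`gamma`), joint successive-state
#' responsibilities (`xi`) and the log evidence for one chain of
#' observation log-likelihoods under fixed parameters. Computed with scaled
#' recursions, numerically stable for chains of at least 10,000 steps.
#'
#' @param log_obs_likelihood T x K matrix of per-timepoint state
#'   log-likelihoods; all entries must be finite.
#' @param initial_distribution length-K probability vector.
#' @param transition_matrix K x K row-stochastic matrix.
#' @return A list with `gamma` (T x K, rows sum to 1), `xi`
#'   ((T-1) x K x K array, each slice sums to 1; `NULL` when T = 1) and
#'   `log_evidence` (scalar).
#' @examples
#' ll <- matrix(log(runif(12)), 6, 2)
#' fb <- forward_backward(ll, c(.5, .5), matrix(.5, 2, 2))
#' rowSums(fb$gamma)
#' @export
forward_backward <- function(log_obs_likelihood, initial_distribution,
                             transition_matrix) {
  logB <- as.matrix(log_obs_likelihood)
  if (any(!is.finite(logB))) abort("non-finite observation log-likelihoods")
  K <- ncol(logB)
  assert_simplex(initial_distribution)
  assert_probability_matrix(transition_matrix)
  if (length(initial_distribution) != K || nrow(transition_matrix) != K) {
    abort("dimension mismatch between likelihoods and parameters")
  }
  res <- .fb_chain(logB, log(pmax(initial_distribution, 1e-300)),
                   log(pmax(transition_matrix, 1e-300)), TRUE)
  xi <- NULL
  if (nrow(logB) > 1) {
    xi <- aperm(res$xi, c(3, 1, 2))  # (T-1) x K x K
  }
  list(gamma = res$gamma, xi = xi, log_evidence = res$log_evidence)
}

#' Most probable hard state sequence (Viterbi)
#'
#' @inheritParams forward_backward
#' @return integer vector of length T with states in `1..K`.
#' @export
viterbi_decode <- function(log_obs_likelihood, initial_distribution,
                           transition_matrix) {
  logB <- as.matrix(log_obs_likelihood)
  if (any(!is.finite(logB))) abort("non-finite observation log-likelihoods")
  assert_simplex(initial_distribution)
  assert_probability_matrix(transition_matrix)
  .viterbi_chain(logB, log(pmax(initial_distribution, 1e-300)),
                 log(pmax(transition_matrix, 1e-300))) + 1L
}
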