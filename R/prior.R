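#' Conjugate prior for the variational Gaussian-observation HMM
#'
#' Dirichlet priors on the initial distribution and each transition-matrix
#' row, and a Normal-Wishart prior on every state's mean and precision.
#' Defaults are weakly informative: unit Dirichlet concentration with a
#' sticky diagonal bonus on transitions (discouraging degenerate fast
#' switching), a broad Normal-Wishart with the minimum-variance-supporting
#' degrees of freedom `N + 2`, and a small mean-precision scale so state
#' means are driven by the data.
#'
#' `wishart_scale` is interpreted on the covariance scale: the prior
#' expected state covariance equals `wishart_scale` (the Wishart scale
#' matrix on the precision is `solve(wishart_scale) / (wishart_dof - N - 1)`
#' when `wishart_dof > N + 1`, else `solve(wishart_scale)`).
#'
#' @param n_regions data dimension `N`.
#' @param n_states number of states `K`.
#' @param dirichlet_transition base concentration for each transition row.
#' @param sticky_bonus added to the diagonal concentration of each row.
#' @param dirichlet_initial concentration for the initial distribution.
#' @param mean_scale prior precision scale `beta0` on state means.
#' @param wishart_dof degrees of freedom, `>= n_regions`.
#' @param wishart_scale SPD matrix, prior expected state covariance.
#' @return A list of class `hmm_prior`.
#' @export
hmm_prior <- function(n_regions, n_states,
                      dirichlet_transition = 1, sticky_bonus = 10,
                      dirichlet_initial = 1, mean_scale = 0.01,
                      wishart_dof = n_regions + 2,
                      wishart_scale = diag(n_regions)) {
  N <- assert_scalar_count(n_regions, "n_regions")
  K <- assert_scalar_count(n_states, "n_states")
  if (dirichlet_transition <= 0 || dirichlet_initial <= 0 || sticky_bonus < 0) {
    abort("Dirichlet concentrations must be positive")
  }
  if (mean_scale <= 0) abort("`mean_scale` must be positive")
  if (wishart_dof < N) abort("`wishart_dof` must be >= n_regions")
  wishart_scale <- as.matrix(wishart_scale)
  if (!isTRUE(all.equal(wishart_scale, t(wishart_scale))) ||
      any(eigen(wishart_scale, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("`wishart_scale` must be symmetric positive definite")
  }
  alpha_trans <- matrix(dirichlet_transition, K, K)
  diag(alpha_trans) <- diag(alpha_trans) + sticky_bonus
  W0inv <- if (wishart_dof > N + 1) wishart_scale * (wishart_dof - N - 1)
           else wishart_scale
  structure(
    list(n_regions = N, n_states = K,
         alpha_trans = alpha_trans,
         alpha_init = rep(dirichlet_initial, K),
         beta0 = mean_scale, m0 = rep(0, N),
         nu0 = as.numeric(wishart_dof), W0inv = W0inv),
    class = "hmm_prior")
}

# log multivariate gamma
lmvgamma <- function(a, N) {
  N * (N - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(N)) / 2))
}

# E[log |Lambda|] under Wishart(W, nu); logdetW passed precomputed
e_logdet_wishart <- function(nu, N, logdetW) {
  sum(digamma((nu + 1 - seq_len(N)) / 2)) + N * log(2) + logdetW
}

kl_dirichlet <- function(a_q, a_p) {
  sq <- sum(a_q)
  lgamma(sq) - sum(lgamma(a_q)) - lgamma(sum(a_p)) + sum(lgamma(a_p)) +
    sum((a_q - a_p) * (digamma(a_q) - digamma(sq)))
}

# KL( NW(m_q, b_q, W_q, nu_q) || NW(m_p, b_p, W_p, nu_p) ), Wishart on the
# precision in the (scale W, dof nu) parametrization with E[Lambda] = nu W.
kl_normal_wishart <- function(m_q, b_q, W_q, nu_q, m_p, b_p, W_p_inv, nu_p,
                              logdetWq, logdetWp) {
  N <- length(m_q)
  elogdet <- e_logdet_wishart(nu_q, N, logdetWq)
  dm <- m_q - m_p
  kl_norm <- 0.5 * (N * (b_p / b_q) - N + N * log(b_q / b_p) +
                      b_p * nu_q * drop(crossprod(dm, W_q %*% dm)))
  tr_pq <- sum(W_p_inv * W_q)  # tr(W_p^{-1} W_q), both symmetric
  kl_wish <- -(nu_p / 2) * (logdetWq - logdetWp) +
    (nu_q / 2) * (tr_pq - N) +
    lmvgamma(nu_p / 2, N) - lmvgamma(nu_q / 2, N) +
    ((nu_q - nu_p) / 2) * sum(digamma((nu_q + 1 - seq_len(N)) / 2))
  kl_norm + kl_wish
}

# Closed-form log marginal likelihood of T iid rows under the Normal-Wishart
# model (exact evidence; the K = 1 variational fit must attain it).
nw_log_marginal <- function(X, prior) {
  X <- as.matrix(X)
  T <- nrow(X); N <- ncol(X)
  b0 <- prior$beta0; nu0 <- prior$nu0; m0 <- prior$m0
  V0 <- prior$W0inv
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2, xbar))
  dm <- xbar - m0
  VT <- V0 + S + (b0 * T / (b0 + T)) * tcrossprod(dm)
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  -T * N / 2 * log(pi) + N / 2 * (log(b0) - log(b0 + T)) +
    nu0 / 2 * ld(V0) - (nu0 + T) / 2 * ld(VT) +
    lmvgamma((nu0 + T) / 2, N) - lmvgamma(nu0 / 2, N)
}
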