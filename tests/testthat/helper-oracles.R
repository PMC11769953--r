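# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (exhaustive enumeration,
# definitional formulas) and never call the implementation paths they check.

# Exhaustive path-sum forward-backward: sums over all K^T state paths.
enum_forward_backward <- function(logB, init, A) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(p) {
    v <- log(init[p[1]]) + logB[1, p[1]]
    if (T > 1) for (t in 2:T) v <- v + log(A[p[t - 1], p[t]]) + logB[t, p[t]]
    v
  })
  mx <- max(lp)
  logZ <- mx + log(sum(exp(lp - mx)))
  w <- exp(lp - logZ)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K)) {
    gamma[t, k] <- sum(w[paths[, t] == k])
  }
  best <- paths[which.max(lp), ]
  list(gamma = gamma, logZ = logZ, map_path = as.integer(best),
       map_logp = max(lp))
}

path_log_prob <- function(path, logB, init, A) {
  v <- log(init[path[1]]) + logB[1, path[1]]
  if (length(path) > 1) {
    for (t in 2:length(path)) {
      v <- v + log(A[path[t - 1], path[t]]) + logB[t, path[t]]
    }
  }
  v
}

random_hmm_instance <- function(K, T) {
  A <- matrix(runif(K * K) + 0.1, K, K)
  A <- A / rowSums(A)
  init <- runif(K) + 0.1
  init <- init / sum(init)
  logB <- matrix(log(runif(T * K) + 1e-3), T, K)
  list(logB = logB, init = init, A = A)
}

# Exact Normal-Wishart evidence via the sequential multivariate Student-t
# posterior-predictive product (independent of the closed-form expression).
student_t_evidence <- function(X, prior) {
  N <- ncol(X)
  b <- prior$beta0; nu <- prior$nu0; m <- prior$m0; V <- prior$W0inv
  total <- 0
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    df <- nu - N + 1
    S <- (b + 1) / (b * df) * V
    d2 <- drop(t(x - m) %*% solve(S) %*% (x - m))
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    total <- total + lgamma((df + N) / 2) - lgamma(df / 2) -
      N / 2 * log(df * base::pi) - 0.5 * ld -
      (df + N) / 2 * log1p(d2 / df)
    bn <- b + 1
    V <- V + tcrossprod(x - m) * b / bn
    m <- (b * m + x) / bn
    b <- bn
    nu <- nu + 1
  }
  total
}

# Definitional BH step-up: find the largest i with p_(i) <= i/m * q.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Average-rank Pearson definition of the Spearman coefficient.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Run-length-encoding lifetime oracle via an explicit scan loop.
lifetime_oracle <- function(path, K) {
  runs <- list()
  start <- 1
  for (t in seq_along(path)[-1]) {
    if (path[t] != path[t - 1]) {
      runs[[length(runs) + 1]] <- c(path[start], t - start)
      start <- t
    }
  }
  runs[[length(runs) + 1]] <- c(path[start], length(path) - start + 1)
  vapply(seq_len(K), function(k) {
    len <- vapply(runs, function(r) if (r[1] == k) r[2] else NA_real_, 0)
    len <- len[!is.na(len)]
    if (length(len)) mean(len) else NA_real_
  }, 0)
}

# Small cohorts reused by several files.
tiny_cohort <- function(seed = 1, K = 2, N = 4, T = 80, n = c(3, 3),
                        sep = 1.5, group_effect = NULL) {
  generate_cohort(cohort_config(
    n_states = K, n_regions = N, n_timepoints = T,
    n_subjects_per_group = n, mean_separation = sep,
    group_effect = group_effect, seed = seed))
}

# A cached small fitted model shared across test files.
.fit_cache <- new.env(parent = emptyenv())
small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    co <- tiny_cohort(seed = 5, K = 3, N = 6, T = 150, n = c(4, 4), sep = 1.5)
    .fit_cache$cohort <- co
    .fit_cache$fit <- vb_fit(co$series, 3, n_init = 2, seed = 5)
  }
  list(fit = .fit_cache$fit, cohort = .fit_cache$cohort)
}
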