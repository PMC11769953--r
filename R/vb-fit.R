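#' Fit a Gaussian-observation HMM by variational Bayes
#'
#' Fits one shared K-state model to all subjects' standardized time series
#' concatenated row-wise; per-subject structure enters only through chain
#' restarts (the forward-backward recursion restarts from the initial
#' distribution at each subject's first row, and no transition is counted
#' across a subject boundary). Each state carries a full-covariance
#' multivariate Gaussian observation model, with conjugate
#' Dirichlet/Normal-Wishart priors (see [hmm_prior()]).
#'
#' The variational free energy `F` (negative evidence lower bound) is
#' computed after every E-step as the negative chain log-evidence under the
#' expected-log parameters plus the KL divergences of the variational
#' parameter posteriors from their priors; it is non-increasing across
#' iterations and is the model-selection criterion of
#' [select_model_order()]. `n_init` deterministic initializations are run
#' (greedy farthest-point center seeding started from a seeded random
#' projection, refined by a few Lloyd iterations) and the run with the
#' lowest final free energy is returned; given the same data and seed the
#' fit is bit-reproducible, and it is invariant to subject order up to
#' floating-point summation.
#'
#' @param series a [subject_ts()] or list of them (same regions).
#' @param n_states number of hidden states K.
#' @param prior an [hmm_prior()]; default built from the data dimensions.
#' @param n_init number of seeded initializations.
#' @param seed master integer seed.
#' @param max_iter maximum VB iterations per initialization.
#' @param tol relative free-energy change declaring convergence.
#' @return An object of class `vbhmm`; see Details. Its `posterior` element
#'   holds the per-subject state responsibilities (`gamma`), decoded
#'   Viterbi paths and the variational parameter posterior.
#' @details The returned object contains `initial_distribution`,
#'   `transition_matrix` and `state_means`/`state_covariances` as posterior
#'   means, `free_energy` and `free_energy_trace`, convergence metadata,
#'   and `posterior` with per-subject `gamma` matrices and `viterbi` paths
#'   (states 1-based). Use [tidy()] / [glance()] for tabular summaries.
#' @examples
#' co <- generate_cohort(cohort_config(n_states = 2, n_regions = 4,
#'   n_timepoints = 80, n_subjects_per_group = c(2, 2), group_effect = NULL))
#' fit <- vb_fit(co$series, n_states = 2, n_init = 2, seed = 1)
#' glance(fit)
#' @export
vb_fit <- function(series, n_states, prior = NULL, n_init = 5, seed = 1,
                   max_iter = 500, tol = 1e-5) {
  series <- assert_series_list(series)
  K <- assert_scalar_count(n_states, "n_states")
  n_init <- assert_scalar_count(n_init, "n_init")
  max_iter <- assert_scalar_count(max_iter, "max_iter")
  X <- do.call(rbind, lapply(series, function(s) s$data))
  Tn <- vapply(series, function(s) nrow(s$data), 1L)
  if (nrow(X) < K) abort("number of states exceeds total timepoints")
  if (any(apply(X, 2, sd) < 1e-12)) {
    abort("all-constant region encountered: degenerate covariance")
  }
  prior <- prior %||% hmm_prior(ncol(X), K)
  if (prior$n_regions != ncol(X) || prior$n_states != K) {
    abort("prior dimensions do not match the data / n_states")
  }
  starts <- cumsum(c(1L, Tn[-length(Tn)]))
  ends <- cumsum(Tn)

  runs <- vector("list", n_init)
  for (j in seq_len(n_init)) {
    gamma0 <- init_responsibilities(X, K, spawn_seed(seed, paste0("init", j)))
    runs[[j]] <- vb_run(X, starts, ends, prior, gamma0, max_iter, tol)
  }
  fe <- vapply(runs, function(r) r$free_energy, 0)
  best <- which.min(fe)
  r <- runs[[best]]

  q <- r$q
  N <- ncol(X)
  A_hat <- q$alpha_trans / rowSums(q$alpha_trans)
  pi_hat <- q$alpha_init / sum(q$alpha_init)
  covs <- lapply(seq_len(K), function(k) {
    S <- solve(q$W[[k]]) / (q$nu[k] - N - 1)
    (S + t(S)) / 2
  })
  labels <- series[[1]]$region_labels
  ids <- vapply(series, function(s) s$subject_id, "")
  gam <- split_rows(r$gamma, starts, ends, ids)
  vit <- decode_paths(r$elog, starts, ends, ids)
  model <- structure(
    list(n_states = K, n_regions = N,
         initial_distribution = pi_hat,
         transition_matrix = A_hat,
         state_means = r$means_hat,
         state_covariances = covs,
         free_energy = r$free_energy,
         free_energy_trace = r$trace,
         n_iter = r$n_iter, converged = r$converged,
         seed = seed, init_index = best,
         init_free_energies = fe,
         prior = prior, q = q, elog = r$elog,
         region_labels = labels, tr_seconds = series[[1]]$tr_seconds,
         subject_ids = ids, n_timepoints = Tn),
    class = "vbhmm")
  model$posterior <- structure(
    list(gamma = gam, viterbi = vit, subject_ids = ids,
         n_states = K, tr_seconds = series[[1]]$tr_seconds),
    class = "state_posterior")
  model
}

split_rows <- function(M, starts, ends, ids) {
  out <- lapply(seq_along(starts), function(i) M[starts[i]:ends[i], , drop = FALSE])
  names(out) <- ids
  out
}

decode_paths <- function(elog, starts, ends, ids) {
  out <- lapply(seq_along(starts), function(i) {
    .viterbi_chain(elog$logB[starts[i]:ends[i], , drop = FALSE],
                   elog$logpi, elog$logA) + 1L
  })
  names(out) <- ids
  out
}

# One full VB optimisation from a responsibility initialization.
vb_run <- function(X, starts, ends, prior, gamma0, max_iter, tol) {
  xi0 <- soft_bigram_counts(gamma0, starts, ends)
  first0 <- colSums(gamma0[starts, , drop = FALSE])
  q <- vb_mstep(X, gamma0, xi0, first0, prior)
  trace <- numeric(0)
  F_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- vb_estep(X, starts, ends, q)
    F <- -e$logZ + vb_kl(q, prior)
    trace <- c(trace, F)
    if (is.finite(F_prev) && abs(F_prev - F) < tol * abs(F)) {
      converged <- TRUE
      F_prev <- F
      break
    }
    F_prev <- F
    q <- vb_mstep(X, e$gamma, e$xi_sum, e$first, prior)
  }
  e <- if (converged) e else vb_estep(X, starts, ends, q)
  list(q = q, gamma = e$gamma, elog = e$elog, free_energy = F_prev,
       trace = trace, n_iter = length(trace), converged = converged,
       means_hat = q$m)
}

soft_bigram_counts <- function(gamma, starts, ends) {
  K <- ncol(gamma)
  xi <- matrix(0, K, K)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      g <- gamma[starts[i]:ends[i], , drop = FALSE]
      xi <- xi + crossprod(g[-nrow(g), , drop = FALSE], g[-1, , drop = FALSE])
    }
  }
  xi
}

# Deterministic, subject-order-invariant initialization: the first center is
# the observation maximizing a seeded random projection, the rest follow by
# greedy farthest-point seeding; a few Lloyd iterations refine the centers
# (all steps depend on the data only through row-order-invariant argmax /
# mean reductions). Converted to soft responsibilities at the end.
init_responsibilities <- function(X, K, seed) {
  T <- nrow(X); N <- ncol(X)
  withr::with_seed(seed, dir <- rnorm(N))
  centers <- matrix(0, K, N)
  centers[1, ] <- X[which.max(drop(X %*% dir)), ]
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (k in 2:K) {
      centers[k, ] <- X[which.max(d2), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
    }
  }
  for (iter in seq_len(10)) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      idx <- which(assign == k)
      if (length(idx)) centers[k, ] <- colMeans(X[idx, , drop = FALSE])
    }
  }
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  d2 <- d2 - apply(d2, 1, min)
  g <- exp(-0.5 * d2 / max(mean(d2), 1e-12))
  g <- g + 1e-4
  g / rowSums(g)
}

# Expected-log parameters and chain posteriors for the current q.
vb_estep <- function(X, starts, ends, q) {
  K <- length(q$nu); N <- ncol(X); T <- nrow(X)
  logpi <- digamma(q$alpha_init) - digamma(sum(q$alpha_init))
  logA <- digamma(q$alpha_trans) - digamma(rowSums(q$alpha_trans))
  logB <- matrix(0, T, K)
  for (k in seq_len(K)) {
    R <- q$cholW[[k]]
    Xc <- sweep(X, 2, q$m[k, ])
    quad <- rowSums((Xc %*% t(R))^2)
    logB[, k] <- 0.5 * q$elogdet[k] - 0.5 * N / q$beta[k] -
      0.5 * q$nu[k] * quad - 0.5 * N * log(2 * pi)
  }
  gamma <- matrix(0, T, K)
  xi_sum <- matrix(0, K, K)
  logZ <- 0
  for (i in seq_along(starts)) {
    res <- .fb_chain(logB[starts[i]:ends[i], , drop = FALSE], logpi, logA, FALSE)
    gamma[starts[i]:ends[i], ] <- res$gamma
    xi_sum <- xi_sum + res$xi_sum
    logZ <- logZ + res$log_evidence
  }
  list(gamma = gamma, xi_sum = xi_sum,
       first = colSums(gamma[starts, , drop = FALSE]),
       logZ = logZ, elog = list(logB = logB, logpi = logpi, logA = logA))
}

# Conjugate parameter updates from responsibilities.
vb_mstep <- function(X, gamma, xi_sum, first, prior) {
  K <- ncol(gamma); N <- ncol(X)
  Nk <- pmax(colSums(gamma), 1e-10)
  xbar <- crossprod(gamma, X) / Nk  # K x N
  beta <- prior$beta0 + Nk
  nu <- prior$nu0 + Nk
  m <- (prior$beta0 * matrix(prior$m0, K, N, byrow = TRUE) + Nk * xbar) / beta
  W <- cholW <- vector("list", K)
  elogdet <- numeric(K)
  for (k in seq_len(K)) {
    Xc <- sweep(X, 2, xbar[k, ])
    Sk <- crossprod(sqrt(gamma[, k]) * Xc)
    dm <- xbar[k, ] - prior$m0
    Winv <- prior$W0inv + Sk +
      (prior$beta0 * Nk[k] / beta[k]) * tcrossprod(dm) +
      1e-6 * diag(N)
    Winv <- (Winv + t(Winv)) / 2
    Wk <- solve(Winv)
    Wk <- (Wk + t(Wk)) / 2
    W[[k]] <- Wk
    cholW[[k]] <- chol(Wk)
    elogdet[k] <- e_logdet_wishart(nu[k], N, 2 * sum(log(diag(cholW[[k]]))))
  }
  list(alpha_init = prior$alpha_init + first,
       alpha_trans = prior$alpha_trans + xi_sum,
       beta = beta, m = m, nu = nu, W = W, cholW = cholW,
       elogdet = elogdet, Nk = Nk)
}

# KL(q || prior) over all parameter blocks.
vb_kl <- function(q, prior) {
  K <- length(q$nu); N <- length(prior$m0)
  kl <- kl_dirichlet(q$alpha_init, prior$alpha_init)
  for (i in seq_len(K)) {
    kl <- kl + kl_dirichlet(q$alpha_trans[i, ], prior$alpha_trans[i, ])
  }
  logdetW0 <- -as.numeric(determinant(prior$W0inv, logarithm = TRUE)$modulus)
  for (k in seq_len(K)) {
    logdetWq <- 2 * sum(log(diag(q$cholW[[k]])))
    kl <- kl + kl_normal_wishart(q$m[k, ], q$beta[k], q$W[[k]], q$nu[k],
                                 prior$m0, prior$beta0, prior$W0inv, prior$nu0,
                                 logdetWq, logdetW0)
  }
  kl
}

#' @export
print.vbhmm <- function(x, ...) {
  cat(sprintf(paste0("<vbhmm> K = %d states, N = %d regions, %d subjects; ",
                     "free energy %.4f (%s after %d iterations, init %d/%d)\n"),
              x$n_states, x$n_regions, length(x$subject_ids), x$free_energy,
              if (x$converged) "converged" else "max_iter reached",
              x$n_iter, x$init_index, length(x$init_free_energies)))
  invisible(x)
}

#' @export
print.state_posterior <- function(x, ...) {
  cat(sprintf("<state_posterior> %d subjects, K = %d states\n",
              length(x$subject_ids), x$n_states))
  invisible(x)
}
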