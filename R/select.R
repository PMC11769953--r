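#' Select the number of hidden states by minimum free energy
#'
#' Fits a variational HMM for every candidate `K` and returns the value
#' attaining the minimum final free energy (ties broken toward smaller K,
#' favouring parsimony). A candidate whose fit fails is recorded with a
#' missing free energy, excluded from the argmin, and reported with a
#' warning.
#'
#' @inheritParams vb_fit
#' @param k_range candidate state counts; default `2:15`.
#' @param verbose print a one-line progress message per candidate.
#' @return An object of class `hmm_selection`: a list with `selected_k`,
#'   `table` (tibble: `n_states`, `free_energy`, `converged`, `n_iter`),
#'   `model` (the winning `vbhmm`, with posteriors) and `models` (per-K
#'   parameter-level fits, posteriors dropped). `tidy()` returns the table;
#'   `autoplot()` draws the free-energy curve.
#' @export
select_model_order <- function(series, k_range = 2:15, prior = NULL,
                               n_init = 5, seed = 1, max_iter = 500,
                               tol = 1e-5, verbose = FALSE) {
  series <- assert_series_list(series)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range) || any(k_range < 1)) abort("invalid `k_range`")
  fits <- vector("list", length(k_range))
  fe <- rep(NA_real_, length(k_range))
  conv <- rep(NA, length(k_range))
  iters <- rep(NA_integer_, length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    pk <- if (is.null(prior)) NULL else prior
    fit <- tryCatch(
      vb_fit(series, K, prior = pk, n_init = n_init,
             seed = spawn_seed(seed, paste0("order-k", K)),
             max_iter = max_iter, tol = tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("fit failed for K = %d: %s", K, conditionMessage(fit)))
      next
    }
    fe[i] <- fit$free_energy
    conv[i] <- fit$converged
    iters[i] <- fit$n_iter
    fits[[i]] <- fit
    if (verbose) {
      message(sprintf("K = %2d: free energy %.3f (%d iterations)",
                      K, fit$free_energy, fit$n_iter))
    }
  }
  if (all(is.na(fe))) abort("every candidate K failed to fit")
  best <- which(fe == min(fe, na.rm = TRUE))[1]  # ties -> smaller K
  model <- fits[[best]]
  light <- lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    f$posterior <- NULL
    f$elog <- NULL
    f
  })
  structure(
    list(selected_k = k_range[best],
         table = tibble::tibble(n_states = k_range, free_energy = fe,
                                converged = conv, n_iter = iters),
         model = model, models = light),
    class = "hmm_selection")
}

#' @export
print.hmm_selection <- function(x, ...) {
  cat(sprintf("<hmm_selection> K in {%s}; selected K = %d by minimum free energy\n",
              paste(range(x$table$n_states), collapse = "..."), x$selected_k))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' Match estimated states to reference states
#'
#' Resolves label switching: finds the permutation of estimated states whose
#' mean vectors best align with the reference's, maximizing the total
#' Pearson correlation between matched mean vectors via an exact
#' branch-and-bound assignment search.
#'
#' @param estimated a `vbhmm`, `hmm_ground_truth`, or K x N matrix of state
#'   means.
#' @param reference same types; must have the same number of states.
#' @return integer permutation `p` with `p[j]` = estimated state matched to
#'   reference state `j`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4)
#' match_states(m[c(2, 3, 1), ], m)
#' @export
match_states <- function(estimated, reference) {
  E <- state_mean_matrix(estimated)
  R <- state_mean_matrix(reference)
  if (nrow(E) != nrow(R)) abort("state counts differ; cannot match")
  K <- nrow(E)
  C <- matrix(0, K, K)  # C[i, j] = cor(estimated i, reference j)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (sd(E[i, ]) < 1e-12 || sd(R[j, ]) < 1e-12) next
    C[i, j] <- cor(E[i, ], R[j, ])
  }
  assignment_max(t(C))  # rows = reference, pick estimated per reference
}

state_mean_matrix <- function(x) {
  if (inherits(x, "vbhmm")) return(x$state_means)
  if (inherits(x, "hmm_ground_truth")) return(x$state_means)
  as.matrix(x)
}

# Exact maximization of sum_j S[j, p[j]] over permutations p by
# best-first branch and bound with per-row maxima as the bound.
assignment_max <- function(S) {
  K <- nrow(S)
  best_val <- -Inf
  best_perm <- integer(K)
  row_max_tail <- rev(cumsum(rev(apply(S, 1, max))))
  recurse <- function(j, used, acc, perm) {
    if (j > K) {
      if (acc > best_val) {
        best_val <<- acc
        best_perm <<- perm
      }
      return(invisible())
    }
    if (acc + row_max_tail[j] <= best_val) return(invisible())
    cand <- setdiff(seq_len(K), used)
    cand <- cand[order(S[j, cand], decreasing = TRUE)]
    for (i in cand) {
      perm[j] <- i
      recurse(j + 1, c(used, i), acc + S[j, i], perm)
    }
  }
  recurse(1L, integer(0), 0, integer(K))
  best_perm
}

#' Decode state posteriors for data under a fitted model
#'
#' Runs forward-backward and Viterbi decoding per subject using the fitted
#' model's variational expected-log parameters (each subject's chain starts
#' from the initial distribution).
#'
#' @param model a `vbhmm`.
#' @param series a [subject_ts()] or list of them (same regions as the fit).
#' @return A `state_posterior`: named lists `gamma` (T x K responsibilities)
#'   and `viterbi` (1-based hard paths).
#' @export
decode_states <- function(model, series) {
  stopifnot(inherits(model, "vbhmm"))
  series <- assert_series_list(series)
  if (ncol(series[[1]]$data) != model$n_regions) {
    abort("region count differs from the fitted model")
  }
  q <- model$q
  K <- model$n_states; N <- model$n_regions
  logpi <- digamma(q$alpha_init) - digamma(sum(q$alpha_init))
  logA <- digamma(q$alpha_trans) - digamma(rowSums(q$alpha_trans))
  gam <- vit <- vector("list", length(series))
  for (i in seq_along(series)) {
    X <- series[[i]]$data
    logB <- matrix(0, nrow(X), K)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, q$m[k, ])
      quad <- rowSums((Xc %*% t(q$cholW[[k]]))^2)
      logB[, k] <- 0.5 * q$elogdet[k] - 0.5 * N / q$beta[k] -
        0.5 * q$nu[k] * quad - 0.5 * N * log(2 * pi)
    }
    gam[[i]] <- .fb_chain(logB, logpi, logA, FALSE)$gamma
    vit[[i]] <- .viterbi_chain(logB, logpi, logA) + 1L
  }
  ids <- vapply(series, function(s) s$subject_id, "")
  names(gam) <- names(vit) <- ids
  structure(list(gamma = gam, viterbi = vit, subject_ids = ids,
                 n_states = K, tr_seconds = series[[1]]$tr_seconds),
            class = "state_posterior")
}
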