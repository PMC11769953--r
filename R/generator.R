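#' Construct the generating ground-truth HMM for a synthetic cohort
#'
#' Builds the known model every downstream stage is validated against: state
#' mean vectors placed along scaled random orthogonal directions (pairwise
#' distance grows with `mean_separation`), state-specific covariances with a
#' mild low-rank structure so state functional-connectivity matrices differ,
#' and one row-stochastic transition matrix per group.
#'
#' The control transition matrix has diagonal `transition_stickiness` with
#' the off-diagonal mass split uniformly. The patient matrix modifies only
#' the rows named by `group_effect`: the rows of the lowered and raised
#' states are solved analytically so that the patient chain's stationary
#' occupancy equals the control's in every other state while moving
#' `fo_delta` stationary mass from the lowered to the raised state; the
#' elevated `trans_from -> trans_to` entry takes its extra mass from the
#' source row's other off-diagonal entries (the entry into the lowered state
#' is depleted first, the remainder pro-rata), leaving the source diagonal
#' -- and hence that state's dwell time -- intact.
#'
#' @param config a [cohort_config()].
#' @return An object of class `hmm_ground_truth` with elements
#'   `initial_distribution`, `transition_matrices` (named list
#'   `patient`/`control`), `state_means` (K x N), `state_covariances`
#'   (list of K SPD matrices), `region_labels`, and the `config`.
#' @examples
#' truth <- make_generating_model(cohort_config(n_regions = 6, seed = 7))
#' rowSums(truth$transition_matrices$patient)
#' @export
make_generating_model <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  K <- config$n_states; N <- config$n_regions
  withr::with_seed(spawn_seed(config$seed, "truth"), {
    # orthogonal mean directions when K <= N, random unit directions otherwise
    G <- matrix(rnorm(N * K), N, K)
    U <- if (K <= N) qr.Q(qr(G)) else sweep(G, 2, sqrt(colSums(G^2)), "/")
    means <- t(U) * config$mean_separation * sqrt(N)  # K x N, row RMS = sep
    covs <- lapply(seq_len(K), function(k) {
      v <- rnorm(N)
      v <- v / sqrt(sum(v^2)) * sqrt(0.5)
      config$noise_scale^2 * (diag(N) + tcrossprod(v))
    })
  })
  A_control <- sticky_transition_matrix(K, config$transition_stickiness)
  A_patient <- patient_transition_matrix(A_control, config)
  labels <- if (N == 116) load_network_table()$region_label else
    paste0("roi_", seq_len(N))
  structure(
    list(initial_distribution = rep(1 / K, K),
         transition_matrices = list(patient = A_patient, control = A_control),
         state_means = means, state_covariances = covs,
         region_labels = labels, config = config),
    class = "hmm_ground_truth")
}

sticky_transition_matrix <- function(K, stickiness) {
  if (K == 1) return(matrix(1, 1, 1))
  A <- matrix((1 - stickiness) / (K - 1), K, K)
  diag(A) <- stickiness
  A
}

# Solve the patient rows so the stationary distribution equals the control's
# uniform 1/K in every non-designated state while moving fo_delta stationary
# mass from the lowered (l) to the raised (r) state. The elevated transition
# entry is applied to its source row first, then the l/r rows are solved
# against the resulting fixed rows, so the occupancy of non-designated
# states is exact by construction. Feasibility (all entries >= 0) bounds how
# sticky the raised state may be at a given delta.
patient_transition_matrix <- function(A_control, config) {
  ge <- config$group_effect
  if (is.null(ge)) return(A_control)
  K <- config$n_states
  if (K < 3) abort("group_effect requires at least 3 states")
  u <- 1 / K
  l <- ge$lower_state; r <- ge$raise_state
  p_l <- u - ge$fo_delta; p_r <- u + ge$fo_delta
  s_l <- ge$lower_stickiness; s_r <- ge$raise_stickiness
  A <- A_control

  # elevated single entry, mass drawn from the source row's off-diagonals
  # (the entry into the lowered state is depleted first, then pro-rata)
  f <- ge$trans_from; to <- ge$trans_to; d <- ge$trans_delta
  if (d > 0) {
    if (f == l || f == r) {
      abort("trans_from must not be one of the occupancy-designated states")
    }
    take_first <- if (l != to && l != f) l else NULL
    avail_first <- if (is.null(take_first)) 0 else A[f, take_first]
    take1 <- min(d, avail_first)
    rest <- d - take1
    others <- setdiff(seq_len(K), c(f, to, take_first))
    pool <- sum(A[f, others])
    if (rest > pool + 1e-12) abort("trans_delta exceeds available off-diagonal mass")
    if (!is.null(take_first)) A[f, take_first] <- A[f, take_first] - take1
    if (rest > 0) A[f, others] <- A[f, others] * (1 - rest / pool)
    A[f, to] <- A[f, to] + d
  }

  # balance equations given the fixed (non-l/r) rows
  fixed <- setdiff(seq_len(K), c(l, r))
  G_l <- sum(A[fixed, l]); G_r <- sum(A[fixed, r])
  A_rl <- (p_l * (1 - s_l) - u * G_l) / p_r
  A_lr <- (p_r * (1 - s_r) - u * G_r) / p_l
  c_j <- u * (1 - colSums(A[fixed, fixed, drop = FALSE]))
  C <- u * (G_l + G_r)
  w_l <- p_l * (1 - s_l - A_lr) / C
  row_l <- w_l * c_j / p_l
  row_r <- (1 - w_l) * c_j / p_r
  ent <- c(A_rl, A_lr, row_l, row_r)
  if (any(ent < -1e-12)) {
    abort(paste0("infeasible group_effect: stationary targets require a ",
                 "negative transition entry; reduce fo_delta or relax the ",
                 "designated stickiness values"))
  }
  A[l, fixed] <- row_l; A[l, l] <- s_l; A[l, r] <- A_lr
  A[r, fixed] <- row_r; A[r, r] <- s_r; A[r, l] <- A_rl
  A / rowSums(A)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalized to a probability vector.
#' @param A row-stochastic K x K matrix.
#' @return length-K stationary probability vector.
#' @export
stationary_distribution <- function(A) {
  assert_probability_matrix(A)
  e <- eigen(t(A))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Sample a hidden state path
#'
#' Draws the first state from the ground truth's initial distribution and
#' each subsequent state from the appropriate group's transition-matrix row.
#'
#' @param truth an `hmm_ground_truth` from [make_generating_model()].
#' @param group `"patient"` or `"control"`.
#' @param length path length (>= 1).
#' @param seed integer seed.
#' @return integer vector of states in `1..K`.
#' @export
sample_state_path <- function(truth, group = c("patient", "control"),
                              length, seed = 1) {
  stopifnot(inherits(truth, "hmm_ground_truth"))
  group <- match.arg(group)
  length <- assert_scalar_count(length, "length", 1L)
  A <- truth$transition_matrices[[group]]
  K <- nrow(A)
  withr::with_seed(seed, {
    path <- integer(length)
    path[1] <- sample.int(K, 1, prob = truth$initial_distribution)
    if (length > 1) {
      for (t in 2:length) path[t] <- sample.int(K, 1, prob = A[path[t - 1], ])
    }
    path
  })
}

#' Sample observations along a state path
#'
#' Row `t` is drawn from the multivariate normal of state `path[t]`
#' (`noise_scale = 0` in the config collapses rows onto the state means).
#'
#' @param truth an `hmm_ground_truth`.
#' @param path integer state path in `1..K`.
#' @param seed integer seed.
#' @param subject_id identifier for the resulting series.
#' @return A [subject_ts()] carrying TR and region labels.
#' @export
sample_observations <- function(truth, path, seed = 1, subject_id = "subject") {
  stopifnot(inherits(truth, "hmm_ground_truth"))
  K <- nrow(truth$state_means)
  if (any(path < 1 | path > K)) abort("path states outside 1..K")
  N <- ncol(truth$state_means)
  chols <- lapply(truth$state_covariances, chol)
  X <- matrix(0, length(path), N)
  withr::with_seed(seed, {
    Z <- matrix(rnorm(length(path) * N), length(path), N)
  })
  for (k in sort(unique(path))) {
    idx <- which(path == k)
    X[idx, ] <- Z[idx, , drop = FALSE] %*% chols[[k]]
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, truth$state_means[k, ], "+")
  }
  subject_ts(X, subject_id, truth$config$tr_seconds,
             region_labels = truth$region_labels)
}

#' Generate a complete synthetic cohort
#'
#' Produces per-subject time series from the generating HMM, the clinical
#' table, and the ground truth. Patient symptom scores are a monotone
#' function of the raised state's true fractional occupancy: a linear map on
#' normalized ranks with strength `clinical_effect`, plus Gaussian noise,
#' rescaled to each scale's range and clipped (IBS-SSS in 0--500 around
#' 224 +/- 50; PHQ-9 in 0--27 around 5 +/- 4; PASS in 0--100 around
#' 29 +/- 16; IBS-QOL in 0--100 around 51 +/- 11). PHQ-9 and PASS share a
#' latent anxiety factor so they correlate with each other. Controls carry
#' missing scores.
#'
#' @param config a [cohort_config()].
#' @return A list of class `state_cohort` with elements `series` (named list
#'   of [subject_ts()]), `clinical` (tibble: subject_id, group, ibs_sss,
#'   phq9, pass, ibs_qol), `true_paths` (named list of integer paths), and
#'   `truth` (the `hmm_ground_truth`).
#' @examples
#' co <- generate_cohort(cohort_config(n_regions = 5, n_timepoints = 50,
#'                                     n_subjects_per_group = c(3, 3)))
#' co$clinical
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- make_generating_model(config)
  n_pat <- config$n_subjects_per_group[1]
  n_con <- config$n_subjects_per_group[2]
  ids <- c(sprintf("ibs_%02d", seq_len(n_pat)),
           sprintf("hc_%02d", seq_len(n_con)))
  groups <- rep(c("patient", "control"), c(n_pat, n_con))
  paths <- series <- vector("list", length(ids))
  names(paths) <- names(series) <- ids
  for (i in seq_along(ids)) {
    paths[[i]] <- sample_state_path(truth, groups[i], config$n_timepoints,
                                    seed = spawn_seed(config$seed, paste0("path-", ids[i])))
    series[[i]] <- sample_observations(truth, paths[[i]],
                                       seed = spawn_seed(config$seed, paste0("obs-", ids[i])),
                                       subject_id = ids[i])
  }
  clinical <- make_clinical_table(config, truth, ids, groups, paths)
  structure(list(series = series, clinical = clinical,
                 true_paths = paths, truth = truth),
            class = "state_cohort")
}

make_clinical_table <- function(config, truth, ids, groups, paths) {
  pat <- which(groups == "patient")
  raise <- if (!is.null(config$group_effect)) config$group_effect$raise_state
           else config$n_states
  ce <- config$clinical_effect
  n <- length(pat)
  out <- tibble::tibble(subject_id = ids,
                        group = factor(groups, c("patient", "control")),
                        ibs_sss = NA_real_, phq9 = NA_real_,
                        pass = NA_real_, ibs_qol = NA_real_)
  if (n == 0) return(out)
  fo_true <- vapply(paths[pat], function(p) mean(p == raise), 0)
  withr::with_seed(spawn_seed(config$seed, "clinical"), {
    z_fo <- as.numeric(scale(rank(fo_true, ties.method = "average")))
    if (all(!is.finite(z_fo))) z_fo <- rep(0, n)  # degenerate: all FO equal
    link <- function(noise) ce * z_fo + sqrt(max(0, 1 - ce^2)) * noise
    anx <- rnorm(n)
    sss <- 223.7 + 50.1 * link(rnorm(n))
    phq <- 5.2 + 4.0 * (0.63 * anx + 0.77 * rnorm(n))
    pas <- 29.4 + 16.2 * (0.63 * anx + 0.77 * rnorm(n))
    qol <- 50.9 + 11.4 * rnorm(n)
  })
  out$ibs_sss[pat] <- pmin(500, pmax(0, round(sss, 1)))
  out$phq9[pat] <- pmin(27, pmax(0, round(phq)))
  out$pass[pat] <- pmin(100, pmax(0, round(pas)))
  out$ibs_qol[pat] <- pmin(100, pmax(0, round(qol, 1)))
  out
}

#' @export
print.state_cohort <- function(x, ...) {
  n <- table(x$clinical$group)
  d <- dim(x$series[[1]])
  cat(sprintf("<state_cohort> %d patients + %d controls, %d x %d series, K = %d states\n",
              n[["patient"]], n[["control"]], d[1], d[2],
              x$truth$config$n_states))
  invisible(x)
}
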