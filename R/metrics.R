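#' Fractional occupancy from state responsibilities
#'
#' The fraction of total time attributed to each state: column means of the
#' T x K responsibility matrix. A one-hot matrix built from a hard path
#' gives the path's occupancy exactly; the soft version is its posterior
#' analogue.
#'
#' @param gamma T x K matrix with rows summing to 1.
#' @return length-K vector summing to 1.
#' @export
fractional_occupancy <- function(gamma) {
  gamma <- as.matrix(gamma)
  if (any(gamma < -1e-9) || any(abs(rowSums(gamma) - 1) > 1e-6)) {
    abort("`gamma` rows must be probability vectors")
  }
  colMeans(gamma)
}

#' Mean state lifetime (dwell time)
#'
#' Mean length of each state's maximal constant runs in the hard path,
#' in TR units and seconds. States never visited get `NA`.
#'
#' @param path integer state path in `1..n_states`.
#' @param tr_seconds sampling interval.
#' @param n_states number of states (defaults to `max(path)`).
#' @return A list with `lt_tr` and `lt_seconds`, each length `n_states`.
#' @examples
#' mean_lifetime(c(1, 1, 2, 2, 2, 1), tr_seconds = 2)
#' @export
mean_lifetime <- function(path, tr_seconds = 2, n_states = max(path)) {
  path <- as.integer(path)
  if (any(path < 1 | path > n_states)) abort("path states outside 1..n_states")
  r <- rle(path)
  lt <- vapply(seq_len(n_states), function(k) {
    len <- r$lengths[r$values == k]
    if (length(len)) mean(len) else NA_real_
  }, 0)
  list(lt_tr = lt, lt_seconds = lt * tr_seconds)
}

#' State switching rate
#'
#' Fraction of consecutive timepoint pairs at which the hard state changes:
#' switches per TR, in `[0, 1]`.
#'
#' @param path integer state path of length >= 2.
#' @return scalar switching rate.
#' @export
switching_rate <- function(path) {
  if (length(path) < 2) abort("switching rate needs at least 2 timepoints")
  mean(diff(as.integer(path)) != 0)
}

#' Empirical transition matrix of a hard path
#'
#' Row `i` holds the normalized successor counts of state `i`. Rows of
#' states never visited as a source (in the first T-1 timepoints) are `NA`
#' rather than imputed.
#'
#' @param path integer state path of length >= 2.
#' @param n_states number of states.
#' @return `n_states` x `n_states` matrix; defined rows sum to 1.
#' @export
empirical_transition_matrix <- function(path, n_states = max(path)) {
  path <- as.integer(path)
  if (length(path) < 2) abort("need at least 2 timepoints")
  if (any(path < 1 | path > n_states)) abort("path states outside 1..n_states")
  A <- matrix(0, n_states, n_states)
  from <- path[-length(path)]; to <- path[-1]
  for (i in seq_along(from)) A[from[i], to[i]] <- A[from[i], to[i]] + 1
  rs <- rowSums(A)
  A <- A / rs
  A[rs == 0, ] <- NA_real_
  A
}

#' Per-subject temporal metrics of fitted brain states
#'
#' Computes, for every subject in a `state_posterior`: fractional occupancy
#' (from the soft responsibilities), mean lifetime in TRs and seconds and
#' the empirical transition matrix (from the hard Viterbi path), and the
#' switching rate. Soft occupancy is the posterior-mean convention;
#' lifetimes and transitions presuppose discrete runs, hence the hard path.
#'
#' @param posterior a `state_posterior` (from [vb_fit()] or
#'   [decode_states()]).
#' @return A tidy tibble with columns `subject_id`, `metric` (one of
#'   `"fo"`, `"lt_tr"`, `"lt_s"`, `"sr"`, `"transition"`), `state`,
#'   `from_state`, `to_state`, and `value`. Lifetime rows of unvisited
#'   states and transition rows from unvisited sources carry `NA` values.
#' @examples
#' co <- generate_cohort(cohort_config(n_states = 2, n_regions = 4,
#'   n_timepoints = 60, n_subjects_per_group = c(2, 2), group_effect = NULL))
#' fit <- vb_fit(co$series, 2, n_init = 1, seed = 1)
#' temporal_metrics(fit$posterior)
#' @export
temporal_metrics <- function(posterior) {
  stopifnot(inherits(posterior, "state_posterior"))
  K <- posterior$n_states
  tr <- posterior$tr_seconds
  rows <- purrr::map2_dfr(
    posterior$subject_ids, seq_along(posterior$subject_ids),
    function(id, i) {
      fo <- fractional_occupancy(posterior$gamma[[i]])
      path <- posterior$viterbi[[i]]
      lt <- mean_lifetime(path, tr, K)
      tm <- empirical_transition_matrix(path, K)
      dplyr::bind_rows(
        tibble::tibble(subject_id = id, metric = "fo",
                       state = seq_len(K), value = fo),
        tibble::tibble(subject_id = id, metric = "lt_tr",
                       state = seq_len(K), value = lt$lt_tr),
        tibble::tibble(subject_id = id, metric = "lt_s",
                       state = seq_len(K), value = lt$lt_seconds),
        tibble::tibble(subject_id = id, metric = "sr",
                       value = switching_rate(path)),
        tibble::tibble(subject_id = id, metric = "transition",
                       from_state = rep(seq_len(K), each = K),
                       to_state = rep(seq_len(K), K),
                       value = as.vector(t(tm))))
    })
  dplyr::relocate(rows, "subject_id", "metric", "state",
                  "from_state", "to_state", "value")
}
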