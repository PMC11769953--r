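#' Tidy a fitted variational HMM
#'
#' @param x a `vbhmm`.
#' @param what `"states"` (long tibble of state means per region),
#'   `"transitions"` (from, to, probability) or `"initial"`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.vbhmm <- function(x, what = c("states", "transitions", "initial"), ...) {
  what <- match.arg(what)
  switch(what,
    states = tibble::tibble(
      state = rep(seq_len(x$n_states), each = x$n_regions),
      region = rep(x$region_labels, x$n_states),
      mean = as.vector(t(x$state_means))),
    transitions = tibble::tibble(
      from_state = rep(seq_len(x$n_states), each = x$n_states),
      to_state = rep(seq_len(x$n_states), x$n_states),
      probability = as.vector(t(x$transition_matrix))),
    initial = tibble::tibble(state = seq_len(x$n_states),
                             probability = x$initial_distribution))
}

#' One-row summary of a fitted variational HMM
#' @param x a `vbhmm`.
#' @param ... unused.
#' @export
glance.vbhmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_regions = x$n_regions,
                 n_subjects = length(x$subject_ids),
                 n_timepoints_total = sum(x$n_timepoints),
                 free_energy = x$free_energy, n_iter = x$n_iter,
                 converged = x$converged, init_index = x$init_index)
}

#' Tidy the free-energy model-order table
#' @param x an `hmm_selection`.
#' @param ... unused.
#' @export
tidy.hmm_selection <- function(x, ...) x$table

#' One-row summary of a model-order selection
#' @param x an `hmm_selection`.
#' @param ... unused.
#' @export
glance.hmm_selection <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k,
                 k_min = min(x$table$n_states),
                 k_max = max(x$table$n_states),
                 n_failed = sum(is.na(x$table$free_energy)),
                 free_energy = x$table$free_energy[
                   x$table$n_states == x$selected_k])
}

#' Tidy group-analysis results
#' @param x a `group_analysis`.
#' @param which `"differences"` or `"correlations"`.
#' @param ... unused.
#' @export
tidy.group_analysis <- function(x, which = c("differences", "correlations"),
                                ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Tidy a state posterior into a long tibble
#' @param x a `state_posterior`.
#' @param ... unused.
#' @return tibble with `subject_id`, `time`, `state`, `gamma`, `viterbi`
#'   (logical: is this the decoded state at that time).
#' @export
tidy.state_posterior <- function(x, ...) {
  purrr::map_dfr(seq_along(x$subject_ids), function(i) {
    g <- x$gamma[[i]]
    tibble::tibble(
      subject_id = x$subject_ids[i],
      time = rep(seq_len(nrow(g)), ncol(g)),
      state = rep(seq_len(ncol(g)), each = nrow(g)),
      gamma = as.vector(g),
      viterbi = rep(x$viterbi[[i]], ncol(g)) == state)
  })
}
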