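#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generating hidden Markov model and cohort
#' design. Defaults emulate the study conditions the package targets: two
#' groups of 35 patients and 31 controls, 190 timepoints per subject at
#' TR = 2 s, a 6-state Gaussian HMM, group-differential occupancy in two
#' designated states, one elevated patient transition probability, and
#' symptom scores positively correlated with the designated state's
#' occupancy. The default region count is 20 so that the full model-order
#' sweep runs in minutes; set `n_regions = 116` for the full parcellation
#' scale (the model is dimension-agnostic).
#'
#' @param n_states number of hidden states `K` (>= 2).
#' @param n_regions number of regions `N` (>= 2).
#' @param n_timepoints timepoints `T` per subject (>= 2).
#' @param tr_seconds sampling interval in seconds.
#' @param n_subjects_per_group integer pair `c(patient, control)`.
#' @param mean_separation scale of the state mean vectors, in observation
#'   standard-deviation units per region (root-mean-square over regions).
#'   0 makes all state means identical.
#' @param transition_stickiness shared diagonal of the control transition
#'   matrix, in (0, 1); off-diagonal mass is split uniformly.
#' @param group_effect `NULL` for no group difference, or a list with
#'   `lower_state`, `raise_state` (distinct state indices whose stationary
#'   occupancy is lowered/raised in patients), `fo_delta` (stationary-mass
#'   shift between them), `lower_stickiness`, `raise_stickiness` (patient
#'   diagonals for those two states), and `trans_from`, `trans_to`,
#'   `trans_delta` (the single elevated patient transition entry).
#' @param clinical_effect monotone link strength, in `[0, 1]`, from the
#'   raised state's true fractional occupancy to the patient symptom score
#'   (approximately the induced Spearman correlation).
#' @param noise_scale observation standard-deviation scale.
#' @param seed master integer seed; all cohort randomness derives from it.
#'
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_regions = 5, n_subjects_per_group = c(4, 4))
#' @export
cohort_config <- function(n_states = 6,
                          n_regions = 20,
                          n_timepoints = 190,
                          tr_seconds = 2,
                          n_subjects_per_group = c(35, 31),
                          mean_separation = 1,
                          transition_stickiness = 0.8,
                          group_effect = default_group_effect(),
                          clinical_effect = 0.7,
                          noise_scale = 1,
                          seed = 1) {
  K <- assert_scalar_count(n_states, "n_states", 1L)
  N <- assert_scalar_count(n_regions, "n_regions", 2L)
  T <- assert_scalar_count(n_timepoints, "n_timepoints", 2L)
  if (length(n_subjects_per_group) != 2) {
    abort("`n_subjects_per_group` must be a pair (patients, controls)")
  }
  n_subjects_per_group <- vapply(n_subjects_per_group, assert_scalar_count,
                                 1L, name = "n_subjects_per_group")
  if (!is.numeric(transition_stickiness) ||
      transition_stickiness <= 0 || transition_stickiness >= 1) {
    abort("`transition_stickiness` must lie in (0, 1)")
  }
  if (mean_separation < 0) abort("`mean_separation` must be >= 0")
  if (noise_scale <= 0) abort("`noise_scale` must be > 0")
  if (clinical_effect < 0 || clinical_effect > 1) {
    abort("`clinical_effect` must lie in [0, 1]")
  }
  if (!is.null(group_effect)) validate_group_effect(group_effect, K)
  structure(
    list(n_states = K, n_regions = N, n_timepoints = T,
         tr_seconds = as.numeric(tr_seconds),
         n_subjects_per_group = n_subjects_per_group,
         mean_separation = as.numeric(mean_separation),
         transition_stickiness = as.numeric(transition_stickiness),
         group_effect = group_effect,
         clinical_effect = as.numeric(clinical_effect),
         noise_scale = as.numeric(noise_scale),
         seed = assert_scalar_count(seed, "seed", 0L)),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_group_effect <- function() {
  list(lower_state = 5L, raise_state = 6L, fo_delta = 0.14,
       lower_stickiness = 0.20, raise_stickiness = 0.87,
       trans_from = 2L, trans_to = 6L, trans_delta = 0.06)
}

validate_group_effect <- function(ge, K) {
  need <- c("lower_state", "raise_state", "fo_delta", "lower_stickiness",
            "raise_stickiness", "trans_from", "trans_to", "trans_delta")
  if (!is.list(ge) || !all(need %in% names(ge))) {
    abort(sprintf("`group_effect` must be a list with fields: %s",
                  paste(need, collapse = ", ")))
  }
  st <- c(ge$lower_state, ge$raise_state, ge$trans_from, ge$trans_to)
  if (any(st < 1 | st > K | st != round(st))) {
    abort(sprintf("group_effect names state indices outside 1..%d", K))
  }
  if (ge$lower_state == ge$raise_state) {
    abort("lower_state and raise_state must differ")
  }
  if (ge$trans_from == ge$trans_to) abort("trans_from and trans_to must differ")
  if (ge$fo_delta < 0 || ge$fo_delta >= 1 / K) {
    abort("`fo_delta` must lie in [0, 1/K)")
  }
  for (f in c("lower_stickiness", "raise_stickiness")) {
    if (ge[[f]] <= 0 || ge[[f]] >= 1) abort(sprintf("`%s` must lie in (0,1)", f))
  }
  if (ge$trans_delta < 0 || ge$trans_delta >= 1) {
    abort("`trans_delta` must lie in [0, 1)")
  }
  invisible(ge)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> K = %d states, N = %d regions, ",
                     "T = %d @ TR %gs, %d patients + %d controls, seed %d\n"),
              x$n_states, x$n_regions, x$n_timepoints, x$tr_seconds,
              x$n_subjects_per_group[1], x$n_subjects_per_group[2], x$seed))
  invisible(x)
}
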