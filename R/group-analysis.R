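#' Two-group analysis of state temporal metrics with clinical correlations
#'
#' Runs the full between-group inference on per-subject temporal metrics:
#' a permutation test per state for fractional occupancy (FO) and lifetime
#' (LT), one for the switching rate, and one per off-diagonal empirical
#' transition entry (self-persistence is LT's domain and is excluded).
#' Benjamini-Hochberg FDR is applied within each metric family (FO across
#' states; LT across states; transitions across entries). Spearman
#' correlations of each state's FO and LT with the clinical scores are
#' computed over patients only (controls carry no scale scores), with FDR
#' within each clinical variable. Subjects missing a state (never visited)
#' are dropped from that state's LT comparison, with a message reporting
#' the count. Deterministic given the master seed.
#'
#' @param metrics tidy metrics tibble from [temporal_metrics()].
#' @param clinical tibble with `subject_id`, `group`
#'   (`"patient"`/`"control"`), and optionally `ibs_sss`, `phq9`, `pass`.
#' @param n_perm permutations per test (default 5000).
#' @param seed master integer seed.
#' @param alpha significance threshold applied to FDR-adjusted p-values.
#' @return A list of class `group_analysis`: `differences` (one row per
#'   test: family, state or from/to pair, `estimate` = patient minus
#'   control mean, `p_perm`, `p_fdr`, group sizes, `significant`),
#'   `correlations` (clinical variable, metric, state, `rho`, `r_squared`,
#'   `p_value`, `p_fdr`, `n`, `significant`), plus `alpha` and `n_perm`.
#' @examples
#' co <- generate_cohort(cohort_config(n_regions = 5, n_timepoints = 100,
#'                                     n_subjects_per_group = c(8, 8)))
#' m <- temporal_metrics(true_path_posterior(co))
#' res <- run_group_analysis(m, co$clinical, n_perm = 200, seed = 1)
#' res$differences
#' @export
run_group_analysis <- function(metrics, clinical, n_perm = 5000, seed = 1,
                               alpha = 0.05) {
  need <- c("subject_id", "metric", "value")
  if (!all(need %in% names(metrics))) {
    abort("`metrics` must come from temporal_metrics()")
  }
  if (!all(c("subject_id", "group") %in% names(clinical))) {
    abort("`clinical` needs `subject_id` and `group` columns")
  }
  dat <- dplyr::left_join(metrics, clinical, by = "subject_id")
  if (anyNA(dat$group)) abort("metrics contain subjects absent from `clinical`")
  counts <- table(clinical$group)
  if (any(counts[c("patient", "control")] < 2)) {
    abort("each group needs at least 2 subjects")
  }

  one_test <- function(df, label) {
    a <- df$value[df$group == "patient"]
    b <- df$value[df$group == "control"]
    dropped <- sum(is.na(df$value))
    if (dropped > 0) {
      message(sprintf("%s: %d subject(s) dropped (state never visited)",
                      label, dropped))
    }
    pt <- permutation_test(a, b, n_perm, seed = spawn_seed(seed, label))
    tibble::tibble(estimate = pt$estimate, p_perm = pt$p_value,
                   n_patient = pt$n_a, n_control = pt$n_b)
  }

  fo <- dat |>
    dplyr::filter(.data$metric == "fo") |>
    dplyr::group_by(state = .data$state) |>
    dplyr::group_modify(~ one_test(.x, paste0("fo-", .y$state))) |>
    dplyr::ungroup() |>
    dplyr::mutate(family = "fo")
  lt <- dat |>
    dplyr::filter(.data$metric == "lt_tr") |>
    dplyr::group_by(state = .data$state) |>
    dplyr::group_modify(~ one_test(.x, paste0("lt-", .y$state))) |>
    dplyr::ungroup() |>
    dplyr::mutate(family = "lt")
  sr <- dat |>
    dplyr::filter(.data$metric == "sr") |>
    one_test("sr") |>
    dplyr::mutate(family = "sr")
  tr <- dat |>
    dplyr::filter(.data$metric == "transition",
                  .data$from_state != .data$to_state) |>
    dplyr::group_by(from_state = .data$from_state,
                    to_state = .data$to_state) |>
    dplyr::group_modify(~ one_test(.x, paste0("tr-", .y$from_state,
                                              "-", .y$to_state))) |>
    dplyr::ungroup() |>
    dplyr::mutate(family = "transition")

  differences <- dplyr::bind_rows(fo, lt, sr, tr) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_fdr = bh_fdr(.data$p_perm)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_fdr < alpha) |>
    dplyr::relocate("family", "state", "from_state", "to_state",
                    "estimate", "p_perm", "p_fdr", "significant")

  correlations <- correlation_block(dat, clinical, alpha)

  structure(list(differences = differences, correlations = correlations,
                 alpha = alpha, n_perm = n_perm, seed = seed),
            class = "group_analysis")
}

correlation_block <- function(dat, clinical, alpha) {
  vars <- intersect(c("ibs_sss", "phq9", "pass"), names(clinical))
  if (!length(vars)) return(tibble::tibble())
  pat <- dat |>
    dplyr::filter(.data$group == "patient",
                  .data$metric %in% c("fo", "lt_tr"))
  if (!nrow(pat)) return(tibble::tibble())
  res <- purrr::map_dfr(vars, function(v) {
    pat |>
      dplyr::group_by(metric = .data$metric, state = .data$state) |>
      dplyr::group_modify(function(g, key) {
        ok <- stats::complete.cases(g$value, g[[v]])
        if (sum(ok) < 3) {
          return(tibble::tibble(rho = NA_real_, r_squared = NA_real_,
                                p_value = NA_real_, n = sum(ok)))
        }
        spearman_cor(g$value, g[[v]])
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(clinical = v)
  })
  res |>
    dplyr::group_by(.data$clinical) |>
    dplyr::mutate(p_fdr = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p_fdr) & .data$p_fdr < alpha) |>
    dplyr::relocate("clinical", "metric", "state", "rho", "r_squared",
                    "p_value", "p_fdr", "significant", "n")
}

#' Build a state posterior from known hard paths
#'
#' Wraps ground-truth (or any externally obtained) hard state paths as a
#' `state_posterior` with one-hot responsibilities, so the metric and
#' statistics stages can run directly on generator output.
#'
#' @param cohort a `state_cohort`, or a named list of integer paths.
#' @param n_states number of states (taken from the cohort's truth when
#'   available).
#' @param tr_seconds sampling interval (likewise).
#' @return a `state_posterior`.
#' @export
true_path_posterior <- function(cohort, n_states = NULL, tr_seconds = NULL) {
  if (inherits(cohort, "state_cohort")) {
    paths <- cohort$true_paths
    n_states <- n_states %||% cohort$truth$config$n_states
    tr_seconds <- tr_seconds %||% cohort$truth$config$tr_seconds
  } else {
    paths <- cohort
    if (is.null(n_states)) abort("`n_states` required for raw path lists")
    tr_seconds <- tr_seconds %||% 2
  }
  gamma <- lapply(paths, function(p) {
    g <- matrix(0, length(p), n_states)
    g[cbind(seq_along(p), p)] <- 1
    g
  })
  structure(list(gamma = gamma, viterbi = paths,
                 subject_ids = names(paths), n_states = n_states,
                 tr_seconds = tr_seconds),
            class = "state_posterior")
}

#' @export
print.group_analysis <- function(x, ...) {
  sig <- sum(x$differences$significant)
  cat(sprintf(paste0("<group_analysis> %d tests (%d significant at ",
                     "p_fdr < %g), %d correlations, %d permutations\n"),
              nrow(x$differences), sig, x$alpha, nrow(x$correlations),
              x$n_perm))
  invisible(x)
}
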