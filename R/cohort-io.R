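#' Write a cohort to a fixture directory
#'
#' Materializes one TSV per subject (T rows x N regions, header = region
#' labels), a `subjects.tsv` with group labels and clinical scores, and a
#' `ground_truth.json` (generator config plus generating matrices as nested
#' arrays). Numeric output is written with 10 significant digits.
#'
#' @param cohort a `state_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "state_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  for (s in cohort$series) {
    write_ts_matrix(s$data, file.path(dir, "timeseries",
                                      paste0(s$subject_id, ".tsv")))
  }
  cl <- cohort$clinical
  cl$group <- as.character(cl$group)
  utils::write.table(cl, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  gt <- list(
    config = unclass(truth$config),
    initial_distribution = truth$initial_distribution,
    transition_matrices = truth$transition_matrices,
    state_means = truth$state_means,
    state_covariances = truth$state_covariances,
    region_labels = truth$region_labels,
    true_paths = cohort$true_paths)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

write_ts_matrix <- function(X, path) {
  df <- as.data.frame(signif(X, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort fixture directory of time-series TSVs
#'
#' Counterpart of [write_cohort()] (the ground truth, if present, is not
#' reloaded). Expects `subjects.tsv` (columns `subject_id`, `group`, plus
#' any clinical columns) and `timeseries/<subject_id>.tsv` matrices.
#'
#' @param dir directory path.
#' @param tr_seconds sampling interval to attach to each series.
#' @return A list with `series` (named list of [subject_ts()]) and
#'   `clinical` (tibble).
#' @export
read_timeseries_dir <- function(dir, tr_seconds = 2) {
  subf <- file.path(dir, "subjects.tsv")
  if (!file.exists(subf)) abort(sprintf("missing subjects table: %s", subf))
  cl <- tibble::as_tibble(utils::read.delim(subf, stringsAsFactors = FALSE))
  if (!all(c("subject_id", "group") %in% names(cl))) {
    abort("subjects.tsv needs columns `subject_id` and `group`")
  }
  cl$group <- factor(cl$group, c("patient", "control"))
  series <- lapply(cl$subject_id, function(id) {
    f <- file.path(dir, "timeseries", paste0(id, ".tsv"))
    if (!file.exists(f)) abort(sprintf("missing time-series file: %s", f))
    X <- tryCatch(as.matrix(utils::read.delim(f, check.names = FALSE)),
                  warning = function(w) abort(sprintf("malformed TSV: %s", f)),
                  error = function(e) abort(sprintf("malformed TSV: %s", f)))
    if (!is.numeric(X) || anyNA(X)) abort(sprintf("malformed TSV: %s", f))
    subject_ts(X, id, tr_seconds, region_labels = colnames(X))
  })
  names(series) <- cl$subject_id
  list(series = series, clinical = cl)
}
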