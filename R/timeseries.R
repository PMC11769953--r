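#' Parcellated subject time series
#'
#' Container for one subject's region-by-time matrix: `T` rows (volumes) by
#' `N` columns (regions), together with the sampling interval (TR) and region
#' labels. All preprocessing and model-fitting functions in the package accept
#' and return this class.
#'
#' @param data numeric matrix, `T` rows (time) by `N` columns (regions), no
#'   missing values.
#' @param subject_id character scalar identifying the subject.
#' @param tr_seconds sampling interval of the rows, in seconds.
#' @param region_labels character vector of length `N`; defaults to existing
#'   column names or `"roi_1"..."roi_N"`.
#' @param standardized logical; `TRUE` once each column has been centred and
#'   scaled (see [standardize_timeseries()]).
#'
#' @return An object of class `subject_ts`.
#' @examples
#' ts <- subject_ts(matrix(rnorm(40), 10, 4), "sub-01", tr_seconds = 2)
#' ts
#' @export
subject_ts <- function(data, subject_id, tr_seconds = 2,
                       region_labels = NULL, standardized = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    abort("time-series matrix must not contain missing or non-finite values")
  }
  if (nrow(data) < 2) abort("time series needs at least 2 timepoints")
  if (ncol(data) < 1) abort("time series needs at least 1 region")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    abort("`tr_seconds` must be a positive scalar")
  }
  region_labels <- region_labels %||% colnames(data) %||%
    paste0("roi_", seq_len(ncol(data)))
  if (length(region_labels) != ncol(data)) {
    abort("`region_labels` length must match the number of regions")
  }
  colnames(data) <- region_labels
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr_seconds = as.numeric(tr_seconds),
         region_labels = as.character(region_labels),
         standardized = isTRUE(standardized)),
    class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %s: %d timepoints x %d regions, TR = %gs%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' @export
dim.subject_ts <- function(x) dim(x$data)

#' @export
as.matrix.subject_ts <- function(x, ...) x$data

is_subject_ts <- function(x) inherits(x, "subject_ts")

assert_series_list <- function(series) {
  if (is_subject_ts(series)) series <- list(series)
  if (!is.list(series) || !length(series) || !all(vapply(series, is_subject_ts, TRUE))) {
    abort("expected a `subject_ts` or a list of them")
  }
  nreg <- vapply(series, function(s) ncol(s$data), 1L)
  if (length(unique(nreg)) != 1) abort("all subjects must share the same regions")
  series
}
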