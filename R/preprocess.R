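#' Extract ROI time series from a 4D functional image and an atlas
#'
#' Averages the functional signal over every voxel sharing an atlas label,
#' producing one column per region. Grids must already be aligned: the three
#' spatial dimensions of `functional` must equal the atlas dimensions (no
#' resampling is performed). Columns are ordered by ascending atlas label and
#' labelled `region_labels[label]` when labels are supplied.
#'
#' @param functional 4D numeric array (x, y, z, time) or a path to a NIfTI
#'   file readable by \pkg{RNifti}.
#' @param atlas 3D integer-labelled array (0 = background) or a NIfTI path.
#' @param subject_id subject identifier carried into the result.
#' @param tr_seconds sampling interval in seconds.
#' @param region_labels optional character vector indexed by atlas label.
#' @return A [subject_ts()] with `T` rows and one column per positive atlas
#'   label present in the atlas.
#' @examples
#' func <- array(rnorm(4 * 4 * 4 * 6), c(4, 4, 4, 6))
#' atlas <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
#' extract_roi_timeseries(func, atlas, subject_id = "s1")
#' @export
extract_roi_timeseries <- function(functional, atlas, subject_id = "subject",
                                   tr_seconds = 2, region_labels = NULL) {
  functional <- read_volume(functional, ndim = 4)
  atlas <- read_volume(atlas, ndim = 3)
  if (!identical(dim(functional)[1:3], dim(atlas))) {
    abort("functional and atlas grids differ in spatial shape; resample upstream")
  }
  if (any(atlas < 0) || any(atlas != round(atlas))) {
    abort("atlas labels must be non-negative integers")
  }
  labels <- sort(unique(as.integer(atlas[atlas > 0])))
  if (!length(labels)) abort("atlas contains no positive labels")
  T <- dim(functional)[4]
  vox <- matrix(functional, ncol = T)  # voxels x time
  lab <- as.integer(atlas)
  out <- matrix(0, T, length(labels))
  for (i in seq_along(labels)) {
    idx <- which(lab == labels[i])
    if (!length(idx)) abort(sprintf("atlas label %d has zero voxels", labels[i]))
    out[, i] <- if (length(idx) == 1) vox[idx, ] else colMeans(vox[idx, , drop = FALSE])
  }
  lbl <- if (is.null(region_labels)) paste0("roi_", labels) else {
    if (max(labels) > length(region_labels)) {
      abort("`region_labels` shorter than the largest atlas label")
    }
    region_labels[labels]
  }
  subject_ts(out, subject_id, tr_seconds, region_labels = lbl)
}

read_volume <- function(x, ndim) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("reading NIfTI paths requires the RNifti package")
    }
    x <- as.array(RNifti::readNifti(x))
  }
  x <- unclass(x)
  if (length(dim(x)) != ndim) abort(sprintf("expected a %dD volume", ndim))
  x
}

#' Discard initial volumes
#'
#' Removes the first `n_discard` rows of a subject's time series, the usual
#' guard against pre-steady-state signal at the start of an fMRI run (e.g.
#' 200 acquired volumes minus 10 discarded leaves 190 analyzed timepoints).
#'
#' @param series a [subject_ts()].
#' @param n_discard number of leading volumes to drop; must be < `T`.
#' @return The shortened `subject_ts`.
#' @export
discard_initial_volumes <- function(series, n_discard = 10) {
  stopifnot(is_subject_ts(series))
  n_discard <- assert_scalar_count(n_discard, "n_discard", min = 0L)
  if (n_discard >= nrow(series$data)) {
    abort(sprintf("n_discard (%d) must be smaller than T (%d)",
                  n_discard, nrow(series$data)))
  }
  if (n_discard == 0) return(series)
  subject_ts(series$data[-seq_len(n_discard), , drop = FALSE],
             series$subject_id, series$tr_seconds,
             series$region_labels, series$standardized)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (two poles per band edge) forward
#' and backward per column, giving zero phase shift so state timing is not
#' displaced. The series is reflection-padded before filtering to suppress
#' edge transients. Default band 0.01--0.08 Hz, the conventional rs-fMRI
#' fluctuation band.
#'
#' @param series a [subject_ts()].
#' @param low_hz,high_hz band edges in Hz; require
#'   `0 <= low_hz < high_hz < 1/(2 * tr_seconds)` (the Nyquist frequency).
#' @return The filtered `subject_ts` (no longer flagged standardized).
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(is_subject_ts(series))
  nyq <- 1 / (2 * series$tr_seconds)
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz < 0 || low_hz >= high_hz || high_hz >= nyq) {
    abort(sprintf("band must satisfy 0 <= low < high < Nyquist (%.4g Hz)", nyq))
  }
  W <- c(max(low_hz, 1e-6) / nyq, high_hz / nyq)
  bf <- signal::butter(2, W, type = "pass")
  X <- sweep(series$data, 2, colMeans(series$data))  # exact DC removal
  T <- nrow(X)
  npad <- min(T - 1L, max(50L, 3L * ceiling(1 / W[1])))
  filt1 <- function(x) {
    # reflect both ends, filter forward then backward, trim
    xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
            2 * x[T] - rev(x[(T - npad):(T - 1)]))
    y <- signal::filter(bf, xp)
    y <- rev(signal::filter(bf, rev(y)))
    y[(npad + 1):(npad + T)]
  }
  out <- apply(X, 2, filt1)
  subject_ts(out, series$subject_id, series$tr_seconds,
             series$region_labels, standardized = FALSE)
}

#' Standardize each region's time course
#'
#' Centres every column to mean zero and scales to unit sample standard
#' deviation (the `n - 1` convention), per subject. Constant columns are
#' centred and left at zero with a warning; downstream activation maps are in
#' these per-subject z-units. Idempotent up to numerical tolerance.
#'
#' @param series a [subject_ts()].
#' @return The standardized `subject_ts` with `standardized = TRUE`.
#' @export
standardize_timeseries <- function(series) {
  stopifnot(is_subject_ts(series))
  X <- series$data
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- apply(Xc, 2, sd)
  const <- s < 1e-12
  if (any(const)) {
    warn(sprintf("%d constant column(s) left at zero after centring: %s",
                 sum(const), paste(series$region_labels[const], collapse = ", ")))
    s[const] <- 1
  }
  subject_ts(sweep(Xc, 2, s, "/"), series$subject_id, series$tr_seconds,
             series$region_labels, standardized = TRUE)
}

#' Run the in-scope temporal preprocessing chain
#'
#' Applies, in this fixed order: discard initial volumes, band-pass filter,
#' standardize. Each step can be toggled; region count and labels are
#' preserved throughout.
#'
#' @param series a [subject_ts()] or list of them.
#' @param n_discard volumes to drop (0 disables).
#' @param bandpass logical; apply [bandpass_filter()]?
#' @param low_hz,high_hz band edges passed to [bandpass_filter()].
#' @param standardize logical; apply [standardize_timeseries()]?
#' @return The processed `subject_ts` (or list).
#' @export
preprocess_timeseries <- function(series, n_discard = 10, bandpass = TRUE,
                                  low_hz = 0.01, high_hz = 0.08,
                                  standardize = TRUE) {
  one <- function(s) {
    if (n_discard > 0) s <- discard_initial_volumes(s, n_discard)
    if (bandpass) s <- bandpass_filter(s, low_hz, high_hz)
    if (standardize) s <- standardize_timeseries(s)
    s
  }
  if (is_subject_ts(series)) one(series) else lapply(assert_series_list(series), one)
}
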