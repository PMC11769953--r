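#' Two-sample nonparametric permutation test
#'
#' Tests a group difference in means by randomly reassigning group labels.
#' The statistic is `mean(a) - mean(b)`; the two-sided p-value uses the
#' add-one convention `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so
#' `p in (0, 1]`. Missing values are removed per sample first.
#'
#' @param a,b numeric samples (non-empty after NA removal).
#' @param n_perm number of label permutations (default 5000).
#' @param seed integer seed; the test is deterministic given it.
#' @return One-row tibble: `estimate` (a minus b), `p_value`, `n_a`, `n_b`,
#'   `n_perm`.
#' @examples
#' permutation_test(rnorm(10), rnorm(10) + 2, n_perm = 500, seed = 1)
#' @export
permutation_test <- function(a, b, n_perm = 5000, seed = 1) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("empty sample after missing-value removal")
  n_perm <- assert_scalar_count(n_perm, "n_perm")
  obs <- mean(a) - mean(b)
  # sorting the pool and always drawing the smaller group size makes the
  # permutation stream invariant to within-group order and to label swaps
  pooled <- sort(c(a, b))
  n <- length(pooled); na <- length(a)
  m <- min(na, n - na)
  tot <- sum(pooled)
  withr::with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      sm <- sum(pooled[sample.int(n, m)])
      stat <- sm / m - (tot - sm) / (n - m)  # sign-free via two-sided compare
      if (abs(stat) >= abs(obs) - 1e-12) exceed <- exceed + 1L
    }
  })
  tibble::tibble(estimate = obs, p_value = (1 + exceed) / (n_perm + 1),
                 n_a = na, n_b = n - na, n_perm = n_perm)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, original
#' order restored. Missing entries stay missing and do not count toward the
#' family size.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' standard t approximation on `rho * sqrt((n - 2) / (1 - rho^2))`.
#' Pairs with a missing value in either variable are removed.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return One-row tibble: `rho`, `r_squared` (= rho^2), `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  rho <- cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, r_squared = rho^2, p_value = p, n = n)
}

#' Severity band of an IBS-SSS score
#'
#' IBS Severity Scoring System bands on the 0--500 scale: below 75
#' sub-threshold (`"none"`), 75--175 `"mild"`, 176--300 `"moderate"`,
#' above 300 `"severe"`.
#'
#' @param score numeric vector in `[0, 500]`.
#' @return ordered factor of bands.
#' @examples
#' classify_ibs_sss(c(50, 120, 223.71, 400))
#' @export
classify_ibs_sss <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 500)) {
    abort("IBS-SSS scores must lie in [0, 500]")
  }
  band <- ifelse(score < 75, "none",
          ifelse(score <= 175, "mild",
          ifelse(score <= 300, "moderate", "severe")))
  factor(band, levels = c("none", "mild", "moderate", "severe"),
         ordered = TRUE)
}

#' Severity band of a PHQ-9 depression score
#'
#' Band floors at 5, 10, 15 and 20 on the 0--27 scale: `"none"` (0--4),
#' `"mild"`, `"moderate"`, `"moderately severe"`, `"severe"`.
#'
#' @param score numeric vector in `[0, 27]`.
#' @return ordered factor of bands.
#' @export
classify_phq9 <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 27)) {
    abort("PHQ-9 scores must lie in [0, 27]")
  }
  cut(score, breaks = c(-Inf, 5, 10, 15, 20, Inf),
      labels = c("none", "mild", "moderate", "moderately severe", "severe"),
      right = FALSE, ordered_result = TRUE)
}
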