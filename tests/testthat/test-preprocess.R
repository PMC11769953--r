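test_that("ROI extraction averages voxels by atlas label", {
  atlas <- array(0L, c(3, 3, 2))
  atlas[1, 1, 1] <- 1L; atlas[2, 1, 1] <- 1L; atlas[3, 3, 2] <- 2L
  func <- array(0, c(3, 3, 2, 4))
  func[1, 1, 1, ] <- 3; func[2, 1, 1, ] <- 3; func[3, 3, 2, ] <- 5
  ts <- extract_roi_timeseries(func, atlas, tr_seconds = 2)
  expect_equal(unname(ts$data), cbind(rep(3, 4), rep(5, 4)))
  expect_equal(ts$region_labels, c("roi_1", "roi_2"))

  # single-voxel regions reproduce the voxel time courses exactly
  set.seed(1)
  func2 <- array(rnorm(3 * 3 * 2 * 5), c(3, 3, 2, 5))
  ts2 <- extract_roi_timeseries(func2, atlas)
  expect_equal(ts2$data[, 2], func2[3, 3, 2, ])

  # brute-force per-label mean oracle on a random volume
  atlas3 <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
  atlas3[1:3, 1, 1] <- 1:3  # ensure all labels present
  func3 <- array(rnorm(4 * 4 * 4 * 6), c(4, 4, 4, 6))
  ts3 <- extract_roi_timeseries(func3, atlas3)
  for (lab in 1:3) {
    for (t in 1:6) {
      vals <- c()
      for (i in 1:4) for (j in 1:4) for (k in 1:4) {
        if (atlas3[i, j, k] == lab) vals <- c(vals, func3[i, j, k, t])
      }
      expect_equal(unname(ts3$data[t, lab]), mean(vals), tolerance = 1e-12)
    }
  }

  expect_error(extract_roi_timeseries(func3, array(1L, c(2, 2, 2))),
               "spatial shape")
})

test_that("discarding initial volumes shortens the series as specified", {
  ts <- subject_ts(matrix(rnorm(200 * 4), 200, 4), "s", 2)
  out <- discard_initial_volumes(ts, 10)
  expect_equal(nrow(out$data), 190)
  expect_equal(out$data, ts$data[11:200, ])
  expect_identical(discard_initial_volumes(ts, 0), ts)
  short <- subject_ts(matrix(rnorm(20), 5, 4), "s", 2)
  expect_error(discard_initial_volumes(short, 5), "smaller than")
})

test_that("band-pass filter has the specified frequency response", {
  T <- 2000; tr <- 2
  tt <- (1:T) * tr
  amp_mid <- function(x) sqrt(2) * sd(x[500:1500])

  pass <- subject_ts(matrix(sin(2 * base::pi * 0.04 * tt), ncol = 1), "a", tr)
  out <- bandpass_filter(pass)
  expect_lt(abs(amp_mid(out$data[, 1]) - 1), 0.05)

  stop_sig <- subject_ts(matrix(sin(2 * base::pi * 0.2 * tt), ncol = 1), "a", tr)
  out2 <- bandpass_filter(stop_sig)
  expect_lt(amp_mid(out2$data[, 1]), 0.1)

  const <- subject_ts(matrix(7.5, 100, 2), "c", tr,
                      region_labels = c("r1", "r2"))
  out3 <- bandpass_filter(const)
  expect_lt(max(abs(out3$data)), 1e-6)
  expect_equal(out3$region_labels, c("r1", "r2"))

  expect_error(bandpass_filter(pass, 0.05, 0.3), "Nyquist")
})

test_that("standardization centres, scales, warns on constants, is idempotent", {
  ts <- subject_ts(cbind(c(1, 2, 3), c(5, 5.5, 9)), "s", 2)
  out <- standardize_timeseries(ts)
  expect_equal(out$data[, 1], c(-1, 0, 1), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(out$data))), 1e-8)
  expect_lt(max(abs(apply(out$data, 2, sd) - 1)), 1e-6)
  again <- standardize_timeseries(out)
  expect_lt(max(abs(again$data - out$data)), 1e-10)
  expect_true(again$standardized)

  cst <- subject_ts(cbind(c(4, 4, 4), c(1, 2, 3)), "s", 2)
  expect_warning(res <- standardize_timeseries(cst), "constant")
  expect_equal(res$data[, 1], c(0, 0, 0))
})

test_that("the preprocessing chain preserves region identity in order", {
  ts <- subject_ts(matrix(rnorm(220 * 3), 220, 3), "s", 2,
                   region_labels = c("x", "y", "z"))
  out <- preprocess_timeseries(ts, n_discard = 10, bandpass = TRUE,
                               standardize = TRUE)
  expect_equal(nrow(out$data), 210)
  expect_equal(out$region_labels, c("x", "y", "z"))
  expect_true(out$standardized)
})
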