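test_that("fractional occupancy counts time correctly", {
  path <- c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3)
  g <- matrix(0, 10, 3); g[cbind(1:10, path)] <- 1
  expect_equal(fractional_occupancy(g), c(0.2, 0.3, 0.5))
  expect_equal(fractional_occupancy(matrix(1 / 4, 6, 4)), rep(0.25, 4))
  set.seed(1)
  r <- matrix(runif(60), 12, 5); r <- r / rowSums(r)
  expect_equal(sum(fractional_occupancy(r)), 1, tolerance = 1e-12)
})

test_that("lifetimes average maximal runs, in TRs and seconds", {
  lt <- mean_lifetime(c(1, 1, 2, 2, 2, 1), tr_seconds = 2)
  expect_equal(lt$lt_tr, c(1.5, 3))
  expect_equal(lt$lt_seconds, c(3, 6))
  lt2 <- mean_lifetime(rep(2L, 7), tr_seconds = 2, n_states = 3)
  expect_equal(lt2$lt_tr, c(NA, 7, NA))
  set.seed(2)
  for (i in 1:20) {
    p <- sample(1:3, 25, replace = TRUE)
    expect_equal(mean_lifetime(p, 2, 3)$lt_tr, lifetime_oracle(p, 3))
  }
})

test_that("switching rate counts state changes per step", {
  expect_equal(switching_rate(c(1, 1, 2, 2, 2, 1)), 0.4)
  expect_equal(switching_rate(rep(3, 9)), 0)
  expect_equal(switching_rate(rep(c(1, 2), 10)), 1)
  expect_error(switching_rate(1), "2 timepoints")
})

test_that("empirical transition matrices normalize successor counts", {
  A <- empirical_transition_matrix(c(1, 1, 2, 2, 2, 1), 2)
  expect_equal(A, matrix(c(0.5, 0.5, 1 / 3, 2 / 3), 2, 2, byrow = TRUE))
  A2 <- empirical_transition_matrix(rep(1L, 5), 2)
  expect_equal(A2[1, ], c(1, 0))
  expect_true(all(is.na(A2[2, ])))
  set.seed(3)
  p <- sample(1:3, 40, replace = TRUE)
  cnt <- matrix(0, 3, 3)
  for (t in 2:40) cnt[p[t - 1], p[t]] <- cnt[p[t - 1], p[t]] + 1
  expect_equal(empirical_transition_matrix(p, 3), cnt / rowSums(cnt))
})

test_that("metric identities tie lifetimes, visits and switching together", {
  set.seed(4)
  for (i in 1:10) {
    p <- sample(1:4, 50, replace = TRUE)
    lt <- mean_lifetime(p, 2, 4)$lt_tr
    visits <- vapply(1:4, function(k) sum(rle(p)$values == k), 0)
    expect_equal(sum(visits * lt, na.rm = TRUE), 50)
    expect_equal(switching_rate(p), (sum(visits) - 1) / (50 - 1))
    # FO from the one-hot gamma equals path occupancy exactly
    g <- matrix(0, 50, 4); g[cbind(1:50, p)] <- 1
    expect_identical(fractional_occupancy(g), tabulate(p, 4) / 50)
  }
})

test_that("temporal_metrics returns one tidy row per quantity", {
  sf <- small_fit()
  m <- temporal_metrics(sf$fit$posterior)
  K <- 3; n <- 8
  expect_equal(nrow(m), n * (3 * K + 1 + K * K))
  expect_setequal(unique(m$metric), c("fo", "lt_tr", "lt_s", "sr",
                                      "transition"))
  fo <- m[m$metric == "fo", ]
  sums <- tapply(fo$value, fo$subject_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  lt <- m[m$metric == "lt_tr", ]
  expect_true(all(lt$value >= 1, na.rm = TRUE))
  sr <- m[m$metric == "sr", ]
  expect_true(all(sr$value >= 0 & sr$value <= 1))
})
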