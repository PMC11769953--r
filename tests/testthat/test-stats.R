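test_that("permutation test handles degenerate and separable samples", {
  r <- permutation_test(c(2, 2, 2), c(2, 2, 2), n_perm = 200, seed = 1)
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)

  # fully separated samples: exact enumeration over C(6,3) = 20 assignments
  a <- c(0, 0, 0); b <- c(10, 10, 10)
  obs <- mean(a) - mean(b)
  combs <- utils::combn(6, 3)
  pool <- c(a, b)
  stats <- apply(combs, 2, function(idx) {
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_exact <- mean(abs(stats) >= abs(obs))
  r2 <- permutation_test(a, b, n_perm = 2000, seed = 2)
  expect_equal(r2$estimate, -10)
  expect_lt(abs(r2$p_value - p_exact), 0.03)
  expect_error(permutation_test(numeric(0), b), "empty")
})

test_that("permutation p is invariant to within-group order and label swaps", {
  set.seed(5)
  a <- rnorm(9); b <- rnorm(12) + 0.8
  r1 <- permutation_test(a, b, n_perm = 400, seed = 3)
  r2 <- permutation_test(sample(a), sample(b), n_perm = 400, seed = 3)
  r3 <- permutation_test(b, a, n_perm = 400, seed = 3)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$p_value, r3$p_value)
  expect_equal(r1$estimate, -r3$estimate)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.005, 0.04, 0.6)), c(0.015, 0.06, 0.6))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(6)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("Spearman correlation matches the average-rank oracle", {
  r <- spearman_cor(1:4, c(10, 20, 30, 40))
  expect_equal(r$rho, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(spearman_cor(1:4, c(40, 30, 20, 10))$rho, -1)
  tied <- spearman_cor(c(1, 1, 2, 3), c(2, 1, 4, 4))
  expect_equal(tied$rho, spearman_oracle(c(1, 1, 2, 3), c(2, 1, 4, 4)),
               tolerance = 1e-12)
  expect_equal(tied$r_squared, tied$rho^2, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    x <- sample(1:5, 10, replace = TRUE); y <- rnorm(10)
    expect_equal(spearman_cor(x, y)$rho, spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "3 complete")
  # missing pairs removed
  expect_equal(spearman_cor(c(1, 2, 3, NA), c(5, 6, 7, 8))$n, 3)
})

test_that("severity bands follow the published scale cut-offs", {
  expect_equal(as.character(classify_ibs_sss(c(50, 75, 120, 175, 223.71,
                                               300, 301, 500))),
               c("none", "mild", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(classify_ibs_sss(501), "0, 500")
  expect_equal(as.character(classify_phq9(c(0, 3, 5, 5.17, 9, 10, 15, 19,
                                            20, 27))),
               c("none", "none", "mild", "mild", "mild", "moderate",
                 "moderately severe", "moderately severe", "severe",
                 "severe"))
  expect_error(classify_phq9(-1), "0, 27")
})
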