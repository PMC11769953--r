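test_that("the analysis tests every family and respects FDR bookkeeping", {
  co <- generate_cohort(cohort_config(seed = 12))
  m <- temporal_metrics(true_path_posterior(co))
  res <- suppressMessages(
    run_group_analysis(m, co$clinical, n_perm = 400, seed = 12))
  d <- res$differences
  K <- 6
  expect_equal(sum(d$family == "fo"), K)
  expect_equal(sum(d$family == "lt"), K)
  expect_equal(sum(d$family == "sr"), 1)
  expect_equal(sum(d$family == "transition"), K * (K - 1))
  expect_true(all(d$p_fdr >= d$p_perm - 1e-12))
  expect_true(all(d$p_perm > 0 & d$p_perm <= 1))
  expect_true(all(d$p_fdr <= 1))
  # FDR applied within family: each family's adjustment reproducible
  for (fam in c("fo", "lt", "transition")) {
    sub <- d[d$family == fam, ]
    expect_equal(sub$p_fdr, bh_fdr(sub$p_perm))
  }

  cr <- res$correlations
  expect_setequal(unique(cr$clinical), c("ibs_sss", "phq9", "pass"))
  expect_equal(nrow(cr), 3 * 2 * K)
  expect_true(all(cr$n <= 35))  # patients only
  expect_equal(cr$r_squared, cr$rho^2, tolerance = 1e-12)

  # deterministic given the master seed
  res2 <- suppressMessages(
    run_group_analysis(m, co$clinical, n_perm = 400, seed = 12))
  expect_identical(res$differences, res2$differences)
})

test_that("the designed group effects are detected on a single cohort", {
  co <- generate_cohort(cohort_config(seed = 30))
  m <- temporal_metrics(true_path_posterior(co))
  res <- suppressMessages(
    run_group_analysis(m, co$clinical, n_perm = 1000, seed = 30))
  d <- res$differences
  ge <- cohort_config()$group_effect
  fo5 <- d[d$family == "fo" & d$state == ge$lower_state, ]
  fo6 <- d[d$family == "fo" & d$state == ge$raise_state, ]
  expect_lt(fo5$estimate, 0); expect_true(fo5$significant)
  expect_gt(fo6$estimate, 0); expect_true(fo6$significant)
  tr <- d[d$family == "transition" & d$from_state == ge$trans_from &
            d$to_state == ge$trans_to, ]
  expect_gt(tr$estimate, 0); expect_true(tr$significant)
  # switching rate not designed to differ
  expect_false(d$significant[d$family == "sr"])
})

test_that("group sizes below two are rejected and NA metrics are dropped", {
  co <- tiny_cohort(seed = 9, K = 2, N = 4, T = 60, n = c(3, 1))
  m <- temporal_metrics(true_path_posterior(co))
  expect_error(run_group_analysis(m, co$clinical, n_perm = 50, seed = 1),
               "at least 2")
})
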