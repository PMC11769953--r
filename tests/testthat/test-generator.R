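test_that("ground truth is reproducible and respects the construction rules", {
  cfg <- cohort_config(n_regions = 8, seed = 7)
  t1 <- make_generating_model(cfg)
  t2 <- make_generating_model(cfg)
  expect_identical(t1, t2)

  flat <- make_generating_model(cohort_config(n_regions = 8,
                                              mean_separation = 0, seed = 7))
  expect_true(max(abs(flat$state_means)) < 1e-12)

  # uniform off-diagonal split at stickiness 0.9, no group effect
  tr <- make_generating_model(cohort_config(
    n_states = 6, n_regions = 8, transition_stickiness = 0.9,
    group_effect = NULL, seed = 1))
  A <- tr$transition_matrices$patient
  expect_identical(A, tr$transition_matrices$control)
  expect_equal(unname(diag(A)), rep(0.9, 6))
  expect_equal(unique(round(A[row(A) != col(A)], 12)), 0.02)

  expect_error(cohort_config(group_effect = list(
    lower_state = 9, raise_state = 6, fo_delta = 0.1,
    lower_stickiness = 0.5, raise_stickiness = 0.9,
    trans_from = 2, trans_to = 6, trans_delta = 0.05)),
    "state indices")
})

test_that("ground-truth invariants hold: stochastic rows, simplex, SPD covariances", {
  truth <- make_generating_model(cohort_config(seed = 3))
  for (A in truth$transition_matrices) {
    expect_lt(max(abs(rowSums(A) - 1)), 1e-12)
    expect_gte(min(A), 0)
  }
  expect_equal(sum(truth$initial_distribution), 1, tolerance = 1e-12)
  for (S in truth$state_covariances) {
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("patient chain differs from control only in the designated occupancies", {
  cfg <- cohort_config(seed = 2)
  truth <- make_generating_model(cfg)
  ge <- cfg$group_effect
  pi_p <- stationary_distribution(truth$transition_matrices$patient)
  pi_c <- stationary_distribution(truth$transition_matrices$control)
  others <- setdiff(seq_len(cfg$n_states), c(ge$lower_state, ge$raise_state))
  expect_equal(pi_p[others], pi_c[others], tolerance = 1e-10)
  expect_lt(pi_p[ge$lower_state], pi_c[ge$lower_state] - 0.05)
  expect_gt(pi_p[ge$raise_state], pi_c[ge$raise_state] + 0.05)
  # the single elevated entry
  expect_equal(truth$transition_matrices$patient[ge$trans_from, ge$trans_to],
               truth$transition_matrices$control[ge$trans_from, ge$trans_to] +
                 ge$trans_delta, tolerance = 1e-12)
})

test_that("state paths follow the chain: absorbing, single-state, stationary", {
  truth <- make_generating_model(cohort_config(n_regions = 5, seed = 1,
                                               group_effect = NULL))
  truth$transition_matrices$control <- diag(6)
  p <- sample_state_path(truth, "control", 50, seed = 4)
  expect_length(unique(p), 1)

  t1 <- make_generating_model(cohort_config(n_states = 1, n_regions = 4,
                                            group_effect = NULL, seed = 1))
  expect_identical(unique(sample_state_path(t1, "patient", 30, seed = 2)), 1L)

  truth2 <- make_generating_model(cohort_config(n_regions = 5, seed = 9))
  p2 <- sample_state_path(truth2, "patient", 10000, seed = 11)
  freq <- tabulate(p2, 6) / 10000
  target <- stationary_distribution(truth2$transition_matrices$patient)
  expect_lt(max(abs(freq - target)), 0.02)
})

test_that("observations follow the state-specific Gaussians", {
  cfg <- cohort_config(n_regions = 5, noise_scale = 1e-8, seed = 1,
                       group_effect = NULL)
  truth <- make_generating_model(cfg)
  path <- sample_state_path(truth, "control", 40, seed = 2)
  obs <- sample_observations(truth, path, seed = 3)
  expect_lt(max(abs(obs$data - truth$state_means[path, ])), 1e-6)
  obs2 <- sample_observations(truth, path, seed = 3)
  expect_identical(obs$data, obs2$data)

  # law of large numbers for the state covariance on a long constant path
  truth2 <- make_generating_model(cohort_config(n_regions = 5, seed = 6,
                                                group_effect = NULL))
  long <- sample_observations(truth2, rep(2L, 5000), seed = 8)
  Shat <- cov(long$data)
  Strue <- truth2$state_covariances[[2]]
  expect_lt(norm(Shat - Strue, "F") / norm(Strue, "F"), 0.1)
})

test_that("cohorts have the study dimensions and clinical-score behaviour", {
  co <- generate_cohort(cohort_config(seed = 21))
  expect_length(co$series, 66)
  expect_equal(dim(co$series[[1]]$data), c(190L, 20L))
  expect_equal(sum(co$clinical$group == "patient"), 35)
  expect_equal(sum(co$clinical$group == "control"), 31)
  expect_true(all(is.na(co$clinical$ibs_sss[co$clinical$group == "control"])))
  pat <- co$clinical[co$clinical$group == "patient", ]
  expect_true(all(pat$ibs_sss >= 0 & pat$ibs_sss <= 500))
  expect_true(all(pat$phq9 >= 0 & pat$phq9 <= 27))

  # determinism
  co2 <- generate_cohort(cohort_config(seed = 21))
  expect_identical(co$series[[17]]$data, co2$series[[17]]$data)
  expect_identical(co$clinical, co2$clinical)

  raise <- cohort_config()$group_effect$raise_state
  fo_true <- vapply(co$true_paths[pat$subject_id],
                    function(p) mean(p == raise), 0)
  # no clinical link -> correlation near zero at n = 35
  co0 <- generate_cohort(cohort_config(clinical_effect = 0, seed = 21))
  pat0 <- co0$clinical[co0$clinical$group == "patient", ]
  fo0 <- vapply(co0$true_paths[pat0$subject_id],
                function(p) mean(p == raise), 0)
  expect_lt(abs(cor(fo0, pat0$ibs_sss, method = "spearman")), 0.25)
  # strong link -> strongly monotone
  co1 <- generate_cohort(cohort_config(clinical_effect = 1, seed = 21))
  pat1 <- co1$clinical[co1$clinical$group == "patient", ]
  fo1 <- vapply(co1$true_paths[pat1$subject_id],
                function(p) mean(p == raise), 0)
  expect_gt(cor(fo1, pat1$ibs_sss, method = "spearman"), 0.8)
})

test_that("cohort fixtures round-trip through the directory format", {
  co <- tiny_cohort(seed = 4, K = 2, N = 3, T = 40, n = c(2, 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_timeseries_dir(dir, tr_seconds = 2)
  expect_named(back$series, names(co$series))
  expect_equal(back$series[[1]]$data, co$series[[1]]$data, tolerance = 1e-9)
  expect_equal(as.character(back$clinical$group),
               as.character(co$clinical$group))
})
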