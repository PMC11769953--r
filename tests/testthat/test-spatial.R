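fake_model <- function(covs, means = NULL, labels = NULL) {
  K <- length(covs); N <- nrow(covs[[1]])
  structure(list(n_states = K, n_regions = N,
                 state_means = means %||% matrix(0, K, N),
                 state_covariances = covs,
                 region_labels = labels %||% paste0("r", seq_len(N))),
            class = "vbhmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("activation maps recover the generating state means", {
  sf <- small_fit()
  perm <- match_states(sf$fit, sf$cohort$truth)
  for (k in 1:3) {
    map <- state_activation_map(sf$fit, perm[k])
    expect_gt(cor(map, sf$cohort$truth$state_means[k, ]), 0.99)
  }
  expect_error(state_activation_map(sf$fit, 9), "range")

  # degenerate truth: zero separation makes every generating map zero
  t0 <- make_generating_model(cohort_config(n_states = 2, n_regions = 4,
    mean_separation = 0, group_effect = NULL, seed = 6))
  m0 <- fake_model(t0$state_covariances, means = t0$state_means)
  expect_lt(max(abs(state_activation_map(m0, 1))), 1e-12)
  expect_lt(max(abs(state_activation_map(m0, 2))), 1e-12)
})

test_that("state FC matrices are correlation matrices of the state covariance", {
  m <- fake_model(list(diag(c(1, 2, 5))))
  expect_equal(unname(state_fc_matrix(m, 1)), diag(3))
  m2 <- fake_model(list(matrix(c(4, 2, 2, 4), 2, 2)))
  C <- state_fc_matrix(m2, 1)
  expect_equal(unname(C), matrix(c(1, 0.5, 0.5, 1), 2, 2))
  expect_equal(C, t(C))
})

test_that("fitted state correlation matrices track the generating ones", {
  sf <- small_fit()
  perm <- match_states(sf$fit, sf$cohort$truth)
  for (k in 1:3) {
    Ck <- state_fc_matrix(sf$fit, perm[k])
    Ct <- cov2cor(sf$cohort$truth$state_covariances[[k]])
    # relative Frobenius error of the recovered correlation structure
    expect_lt(norm(unname(Ck) - Ct, "F") / norm(Ct, "F"), 0.2)
  }
})

test_that("network block means follow the pairwise definition", {
  nets <- tibble::tibble(
    region_label = paste0("r", 1:6),
    network = factor(c("SMN", "SMN", "DMN", "DMN", "DMN", "VIS"),
                     levels = network_tags))
  I6 <- diag(6); dimnames(I6) <- list(paste0("r", 1:6), paste0("r", 1:6))
  b <- network_block_summary(I6, nets)
  expect_equal(b["SMN", "SMN"], 0)
  expect_equal(b["SMN", "DMN"], 0)
  expect_true(is.na(b["VIS", "VIS"]))  # single-region network
  expect_true(all(is.na(b["AUD", ])))  # absent network

  ones <- matrix(1, 6, 6); dimnames(ones) <- dimnames(I6)
  b2 <- network_block_summary(ones, nets)
  expect_equal(b2["DMN", "DMN"], 1)
  expect_equal(b2["SMN", "VIS"], 1)

  # double-loop oracle on a random symmetric matrix
  set.seed(9)
  M <- matrix(rnorm(36), 6, 6); M <- (M + t(M)) / 2
  dimnames(M) <- dimnames(I6)
  b3 <- network_block_summary(M, nets)
  tags <- c("SMN", "SMN", "DMN", "DMN", "DMN", "VIS")
  oracle <- function(a, bb) {
    vals <- c()
    for (i in 1:6) for (j in 1:6) {
      if (i != j && tags[i] == a && tags[j] == bb) vals <- c(vals, M[i, j])
    }
    mean(vals)
  }
  expect_equal(b3["SMN", "DMN"], oracle("SMN", "DMN"))
  expect_equal(b3["DMN", "DMN"], oracle("DMN", "DMN"))
  expect_equal(b3, t(b3))

  M2 <- M; colnames(M2)[1] <- "unknown_region"; rownames(M2)[1] <- "unknown_region"
  expect_error(network_block_summary(M2, nets), "unlabelled")
})

test_that("activation maps survive a JSON serialization round trip", {
  sf <- small_fit()
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(state_activation_map(sf$fit, 1)), f,
                       auto_unbox = TRUE, digits = NA)
  back <- unlist(jsonlite::read_json(f))
  expect_equal(back, state_activation_map(sf$fit, 1), tolerance = 1e-12)
})
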