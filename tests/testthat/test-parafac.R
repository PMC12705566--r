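test_that("an exact rank-1 tensor is recovered perfectly and deterministically", {
  fx <- get_fixture_suite()
  m <- fit_parafac(fx$rank1$tensor, 1, n_restarts = 2, seed = 3)
  expect_lt(m$fit_error, 1e-6)
  expect_gt(abs(tucker_congruence(m$ex_loadings[, 1], fx$rank1$v)), 0.9999)
  expect_gt(abs(tucker_congruence(m$em_loadings[, 1], fx$rank1$w)), 0.9999)
  expect_gt(abs(tucker_congruence(m$sample_scores[, 1], fx$rank1$u)), 0.9999)

  m2 <- fit_parafac(fx$rank1$tensor, 1, n_restarts = 2, seed = 3)
  expect_identical(m[names(m) != "fit_trace"], m2[names(m2) != "fit_trace"])
})

test_that("a noiseless 3-component tensor is recovered with congruence >= 0.99", {
  fx <- get_fixture_suite()
  m <- fit_parafac(fx$rank3$tensor, 3, n_restarts = 5, seed = 3)
  expect_lt(m$fit_error, 1e-5)
  truthB <- sweep(fx$rank3$B, 2, sqrt(colSums(fx$rank3$B^2)), "/")
  truthC <- sweep(fx$rank3$C, 2, sqrt(colSums(fx$rank3$C^2)), "/")
  pairs <- eemstress:::match_components(m$ex_loadings, m$em_loadings, truthB, truthC)
  expect_true(all(pairs$congruence >= 0.99))
})

test_that("ALS fit error is monotone non-increasing across iterations", {
  fx <- get_fixture_suite()
  set.seed(8)
  X <- fx$rank3$tensor + array(rnorm(length(fx$rank3$tensor), 0, 0.05), dim(fx$rank3$tensor))
  X[X < 0] <- 0
  for (F in c(2, 4)) {
    m <- fit_parafac(X, F, n_restarts = 1, seed = 5, max_iter = 200)
    expect_true(all(diff(m$fit_trace) <= 1e-10))
    expect_gte(m$fit_error, 0)
    expect_lte(m$fit_error, 1)
  }
})

test_that("invalid ranks and non-finite tensors are rejected", {
  fx <- get_fixture_suite()
  expect_error(fit_parafac(fx$rank3$tensor, 11), "rank")
  X <- fx$rank3$tensor
  X[1, 1, 1] <- NA
  expect_error(fit_parafac(X, 2), "non-finite")
})

test_that("loadings are unit-norm nonnegative with magnitude absorbed into scores", {
  fx <- get_fixture_suite()
  m <- fit_parafac(fx$rank3$tensor, 3, n_restarts = 3, seed = 4)
  expect_equal(colSums(m$ex_loadings^2), rep(1, 3), tolerance = 1e-9)
  expect_equal(colSums(m$em_loadings^2), rep(1, 3), tolerance = 1e-9)
  expect_true(all(m$ex_loadings >= 0) && all(m$em_loadings >= 0) &&
                all(m$sample_scores >= 0))
  # reconstruction is invariant under the normalisation
  Xhat <- cp_compose(m$sample_scores, m$ex_loadings, m$em_loadings)
  expect_equal(sum((fx$rank3$tensor - Xhat)^2) / sum(fx$rank3$tensor^2),
               m$fit_error, tolerance = 1e-6)
})

test_that("fit error matches an independent plain CP-ALS oracle", {
  set.seed(14)
  A <- matrix(runif(20 * 3, 0.1, 1), 20, 3)
  B <- matrix(runif(10 * 3, 0.1, 1), 10, 3)
  C <- matrix(runif(15 * 3, 0.1, 1), 15, 3)
  X <- cp_compose(A, B, C) +
    array(abs(rnorm(20 * 10 * 15, 0, 0.02)), c(20, 10, 15))
  ours <- fit_parafac(X, 3, n_restarts = 5, seed = 6)
  oracle <- plain_cp_als(X, 3, n_iter = 400)
  expect_lt(abs(ours$fit_error - oracle$fit_error), 1e-3)
})

test_that("core consistency is ~100 at the true rank and collapses when over-factored", {
  fx <- get_fixture_suite()
  m3 <- fit_parafac(fx$rank3$tensor, 3, n_restarts = 5, seed = 3)
  cc3 <- core_consistency(m3, fx$rank3$tensor)
  expect_gt(as.numeric(cc3), 99)
  expect_false(attr(cc3, "degenerate"))

  m1 <- fit_parafac(fx$rank1$tensor, 1, n_restarts = 2, seed = 3)
  expect_equal(as.numeric(core_consistency(m1, fx$rank1$tensor)), 100,
               tolerance = 1e-6)

  set.seed(2)
  Xn <- fx$rank3$tensor +
    array(abs(rnorm(length(fx$rank3$tensor), 0, 0.02)), dim(fx$rank3$tensor))
  m6 <- fit_parafac(Xn, 6, n_restarts = 3, seed = 3)
  cc6 <- core_consistency(m6, Xn)
  if (attr(cc6, "degenerate")) expect_true(is.na(as.numeric(cc6)))
  else expect_lt(as.numeric(cc6), 50)
})

test_that("split-half similarity is high for a stable noiseless decomposition", {
  fx <- get_fixture_suite()
  s <- split_half(fx$rank3$tensor, 3, n_splits = 2, seed = 5)
  expect_gt(as.numeric(s), 99)
  s2 <- split_half(fx$rank3$tensor, 3, n_splits = 2, seed = 5)
  expect_identical(as.numeric(s), as.numeric(s2))
  expect_length(attr(s, "per_split"), 2)
  expect_error(split_half(fx$rank3$tensor[1:3, , ], 2), "at least 4")
})

test_that("rank selection returns one diagnostic row per candidate and finds rank 1", {
  fx <- get_fixture_suite()
  sel <- select_rank(fx$rank1$tensor, 1:3, seed = 4, n_restarts = 2,
                     n_splits = 2, max_iter = 150)
  expect_equal(nrow(sel$diagnostics), 3)
  expect_equal(sel$chosen, 1)
  expect_error(select_rank(fx$rank1$tensor, integer(0)), "non-empty")
})

test_that("score projection reproduces training scores and is linear", {
  gen <- generate_eem_dataset(
    noise = noise_model(additive_gaussian_sigma = 1),
    n_per_group = 4, grid = eem_grid(250, 450, 10, 300, 600, 5),
    seed = 8, scatter = FALSE)
  X <- dataset_tensor(gen$dataset)
  m <- fit_parafac(X, 5, n_restarts = 3, seed = 2)
  proj <- project_scores(m, gen$dataset)
  rel <- abs(proj - m$sample_scores) / pmax(m$sample_scores, 1e-9)
  expect_lt(stats::median(rel), 0.01)
  expect_true(all(rel < 0.05))

  vec <- matrix(as.numeric(gen$dataset$samples[[1]]$intensities), 1)
  p1 <- project_scores(m, vec)
  p2 <- project_scores(m, 2 * vec)
  expect_equal(p2, 2 * p1, tolerance = 1e-6)
  expect_equal(as.numeric(project_scores(m, 0 * vec)), rep(0, 5))
})
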