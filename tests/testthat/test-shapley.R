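linear_model <- function(beta) function(m) as.numeric(m %*% beta)

test_that("the value function masks features against the background", {
  set.seed(3)
  beta <- rnorm(4)
  f <- linear_model(beta)
  x <- stats::setNames(rnorm(4), paste0("f", 1:4))
  bg <- stats::setNames(rnorm(4), paste0("f", 1:4))
  expect_equal(value_function(f, x, 1:4, bg), as.numeric(sum(beta * x)))
  expect_equal(value_function(f, x, integer(0), bg), as.numeric(sum(beta * bg)))
  for (i in 1:4) {
    expect_equal(value_function(f, x, i, bg),
                 sum(beta * bg) + beta[i] * (x[i] - bg[i]),
                 ignore_attr = TRUE)
  }
  # names work too; unknown features error
  expect_equal(value_function(f, x, c("f2", "f3"), bg),
               value_function(f, x, 2:3, bg))
  expect_error(value_function(f, x, "f9", bg), "unknown feature")
  expect_error(value_function(f, x, 7, bg), "unknown feature")
})

test_that("exact Shapley satisfies the linear closed form and the axioms", {
  set.seed(5)
  beta <- c(1.5, -2, 0, 0.7)  # feature 3 is a dummy
  f <- linear_model(beta)
  x <- stats::setNames(rnorm(4), paste0("f", 1:4))
  bg <- stats::setNames(rnorm(4), paste0("f", 1:4))
  att <- exact_shapley(f, x, bg)
  expect_equal(att$phi, beta * (x - bg), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(att$phi[["f3"]], 0)
  expect_equal(att$base_value + sum(att$phi), att$fx, tolerance = 1e-6)
  expect_equal(att$fx, sum(beta * x), ignore_attr = TRUE)

  # symmetry: interchangeable features with equal values get equal phi
  g <- function(m) as.numeric(m[, 1] * m[, 2] + m[, 1] + m[, 2] + 2 * m[, 3])
  xs <- c(a = 1.3, b = 1.3, c = 0.5)
  bgs <- c(a = 0.2, b = 0.2, c = 0.1)
  atts <- exact_shapley(g, xs, bgs)
  expect_equal(atts$phi[["a"]], atts$phi[["b"]], tolerance = 1e-12)

  expect_error(exact_shapley(f, rnorm(16), rnorm(16)), "sampled_shapley")
})

test_that("exact Shapley matches brute-force permutation enumeration", {
  set.seed(11)
  for (p in c(3, 5)) {
    # random nonlinear model: quadratic with interactions
    W <- matrix(rnorm(p * p), p)
    b <- rnorm(p)
    f <- function(m) as.numeric(rowSums((m %*% W) * m) + m %*% b)
    x <- stats::setNames(rnorm(p), paste0("f", seq_len(p)))
    bg <- stats::setNames(rnorm(p), paste0("f", seq_len(p)))
    att <- exact_shapley(f, x, bg)
    bf <- brute_force_shapley(f, x, bg)
    expect_equal(att$phi, bf, tolerance = 1e-10)
    expect_equal(att$base_value + sum(att$phi), att$fx, tolerance = 1e-6)
  }
})

test_that("sampled Shapley agrees with exact within Monte-Carlo error", {
  set.seed(19)
  p <- 7
  W <- matrix(rnorm(p * p, 0, 0.5), p)
  f <- function(m) as.numeric(rowSums((m %*% W) * m))
  x <- stats::setNames(rnorm(p), paste0("f", seq_len(p)))
  bg <- stats::setNames(rep(0, p), paste0("f", seq_len(p)))
  exact <- exact_shapley(f, x, bg)
  samp <- sampled_shapley(f, x, bg, n_permutations = 300, seed = 7)
  z <- (samp$phi - exact$phi) / samp$se
  # per-feature z-scores bounded (4 se allows for 7 simultaneous checks)
  expect_true(all(abs(z) <= 4))
  expect_lt(mean(abs(z)), 2.5)
  expect_equal(samp$base_value + sum(samp$phi), samp$fx, tolerance = 1e-9)
  # reproducible given seed
  samp2 <- sampled_shapley(f, x, bg, n_permutations = 300, seed = 7)
  expect_identical(samp$phi, samp2$phi)
  # standard errors shrink like 1/sqrt(2) when permutations double
  se1 <- mean(sampled_shapley(f, x, bg, 250, seed = 3)$se)
  se2 <- mean(sampled_shapley(f, x, bg, 500, seed = 3)$se)
  expect_equal(se2 / se1, 1 / sqrt(2), tolerance = 0.25)
  expect_error(sampled_shapley(f, x, bg, 0), "n_permutations")
})

test_that("importance summaries rank the discriminative feature first", {
  # logistic-style model driven by feature 2 only
  f_true <- function(m) stats::plogis(3 * (m[, 2] - 1))
  set.seed(23)
  n <- 30
  X <- matrix(rnorm(3 * n, 1, 0.5), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  bg <- colMeans(X)
  atts <- lapply(seq_len(n), function(i) exact_shapley(f_true, X[i, ], bg))
  cls <- rep(c("0", "10", "100"), each = 10)
  summ <- importance_summary(atts, cls)
  overall <- summ[summ$class == "overall", ]
  expect_equal(overall$feature[overall$rank == 1], "v")
  expect_equal(sort(unique(summ$class)), c("0", "10", "100", "overall"))
  expect_equal(sum(summ$class != "overall") / 3, 3)  # 3 features per class block

  # exact ties break by catalog (column) order
  f0 <- function(m) rep(1, nrow(m))
  att0 <- exact_shapley(f0, c(a = 1, b = 2, c = 3), c(a = 0, b = 0, c = 0))
  s0 <- importance_summary(list(att0))
  expect_equal(s0$rank, 1:3)
  expect_error(importance_summary(list()), "at least one")
})

test_that("a trained classifier's attribution finds the planted component", {
  # dataset where only a humic component centred in peak C's window
  # responds to dose, so peak C should carry the model's decisions
  cat5 <- default_fluorophore_catalog()
  cat5[[3]] <- fluorophore("C3_humic", ex_center = 340, ex_sigma = 18,
                           em_center = 440, em_sigma = 18,
                           base_amplitude = 700)
  gen <- generate_eem_dataset(
    catalog = cat5,
    effects = default_treatment_effects(cat5, affected_components = "C3_humic"),
    noise = noise_model(additive_gaussian_sigma = 5),
    n_per_group = 6, seed = 41)
  pp <- preprocess_dataset(gen$dataset)
  pt <- build_peak_table(pp)
  keep <- pt$polymer %in% c("CONTROL", "PS")
  feats <- feature_matrix(pt[keep, ])
  labels <- pt$concentration[keep]
  cl <- train_attention_classifier(
    feats, labels,
    attention_config(embed_dim = 16, n_heads = 2, depth = 1, mlp_hidden = 32,
                     epochs = 60, learning_rate = 5e-3, seed = 6),
    type = "features")
  bg <- colMeans(feats)
  idx <- seq(1, nrow(feats), by = 2)
  atts <- lapply(idx, function(i) {
    exact_shapley(class_prob_fn(cl, as.character(labels[i])), feats[i, ], bg)
  })
  summ <- importance_summary(atts, labels[idx])
  overall <- summ[summ$class == "overall", ]
  expect_equal(overall$feature[overall$rank == 1], "C")
})
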