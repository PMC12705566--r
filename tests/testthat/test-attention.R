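test_that("scaled dot-product attention matches the closed formula", {
  # singleton key set: output is V's single row regardless of Q
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(c(1, 5), 1, 2)
  V <- matrix(c(2, -1, 7), 1, 3)
  out <- scaled_dot_product_attention(Q, K, V)
  expect_equal(unname(out), matrix(rep(V, each = 3), 3, 3), ignore_attr = TRUE)

  # zero queries: uniform weights, output = column means of V
  set.seed(3)
  V2 <- matrix(rnorm(12), 4, 3)
  out2 <- scaled_dot_product_attention(matrix(0, 2, 5), matrix(rnorm(20), 4, 5), V2)
  expect_equal(unname(out2), matrix(rep(colMeans(V2), each = 2), 2, 3),
               ignore_attr = TRUE)

  # 2x2 worked case against the direct formula
  Q3 <- diag(2); K3 <- diag(2); V3 <- matrix(c(1, 0, 0, 1), 2, 2)
  S <- Q3 %*% t(K3) / sqrt(2)
  W <- exp(S) / rowSums(exp(S))
  expect_equal(unname(scaled_dot_product_attention(Q3, K3, V3)),
               unname(W %*% V3), ignore_attr = TRUE)

  expect_error(scaled_dot_product_attention(matrix(0, 2, 3), matrix(0, 2, 2),
                                            matrix(0, 2, 2)), "mismatch")
  expect_error(scaled_dot_product_attention(matrix(0, 2, 3), matrix(0, 2, 3),
                                            matrix(0, 3, 2)), "rows")
})

test_that("attention weights are row-stochastic and sharpen with logit gaps", {
  set.seed(7)
  out <- scaled_dot_product_attention(matrix(rnorm(40), 8, 5),
                                      matrix(rnorm(30), 6, 5),
                                      matrix(rnorm(24), 6, 4))
  W <- attr(out, "weights")
  expect_equal(rowSums(W), rep(1, 8), tolerance = 1e-6)
  expect_true(all(W >= 0))
  # a larger gap between the two logits gives a more peaked weight
  peak <- function(scale) {
    Q <- matrix(c(scale, 0), 1, 2)
    K <- rbind(c(1, 0), c(0, 1))
    max(attr(scaled_dot_product_attention(Q, K, K), "weights"))
  }
  expect_true(peak(1) < peak(2) && peak(2) < peak(5))
})

test_that("multi-head attention reduces to single-head with identity maps", {
  set.seed(5)
  x <- matrix(rnorm(24), 6, 4)
  idw <- list(Wq = diag(4), Wk = diag(4), Wv = diag(4), Wo = diag(4))
  expect_equal(multi_head_attention(x, idw, h = 1),
               unclass(scaled_dot_product_attention(x, x, x)),
               ignore_attr = TRUE)
  # shape preservation with random learned maps, h = 2
  w <- list(Wq = matrix(rnorm(16), 4), Wk = matrix(rnorm(16), 4),
            Wv = matrix(rnorm(16), 4), Wo = matrix(rnorm(16), 4))
  y <- multi_head_attention(x, w, h = 2)
  expect_equal(dim(y), dim(x))
  # permutation equivariance (no positional terms inside the op)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(multi_head_attention(x[perm, ], w, h = 2), y[perm, ],
               tolerance = 1e-12)
})

test_that("patchify produces the padded token counts plus a class token", {
  cfg <- attention_config()
  p2 <- patchify(matrix(rnorm(67 * 511), 67, 511), cfg)
  expect_equal(nrow(p2$patches), ceiling(67 / 8) * ceiling(511 / 32)) # 144
  expect_equal(nrow(p2$tokens), 145)
  expect_equal(ncol(p2$tokens), cfg$embed_dim)

  p1 <- patchify(rnorm(511), cfg)
  expect_equal(nrow(p1$patches), 32)
  expect_equal(nrow(p1$tokens), 33)

  pz <- patchify(rep(0, 511), cfg)
  expect_true(all(pz$patches == 0))

  pf <- patchify(rnorm(7), cfg, type = "features")
  expect_equal(nrow(pf$tokens), 2)

  expect_error(patchify(rnorm(5), attention_config(patch_size_1d = 16)), "exceeds")
  expect_error(attention_config(embed_dim = 10, n_heads = 4), "divisible")
  expect_error(attention_config(dropout_rate = 1), "dropout")
})

test_that("encoder blocks preserve shape and layer-norm standardises rows", {
  cfg <- attention_config(embed_dim = 8, n_heads = 2, mlp_hidden = 12)
  set.seed(9)
  w <- with_seed(4, eemstress:::init_block(8, 12))
  x <- matrix(rnorm(40), 5, 8)
  y <- encoder_block(x, w, h = 2)
  expect_equal(dim(y), dim(x))
  y2 <- encoder_block(y, w, h = 2)
  expect_equal(dim(y2), dim(x))
  ln <- eemstress:::layernorm_fwd(x, rep(1, 8), rep(0, 8))
  expect_equal(rowMeans(ln$y), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(ln$y, 1, function(r) mean(r^2)), rep(1, 5), tolerance = 1e-4)
})

test_that("the classifier fits a separable toy problem and is deterministic", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40 * 5, 0), 40, 5), matrix(rnorm(40 * 5, 3), 40, 5))
  y <- rep(c("low", "high"), each = 40)
  cfg <- attention_config(embed_dim = 16, n_heads = 2, depth = 1,
                          mlp_hidden = 32, epochs = 50, learning_rate = 5e-3,
                          seed = 2)
  cl <- train_attention_classifier(x, y, cfg, type = "features")
  expect_equal(mean(predict(cl, x, type = "class") == y), 1)
  probs <- predict(cl, x, type = "prob")
  expect_equal(rowSums(probs), rep(1, 80), tolerance = 1e-9)
  # deterministic retrain, bit-stable repeated inference
  cl2 <- train_attention_classifier(x, y, cfg, type = "features")
  expect_identical(predict(cl, x), predict(cl2, x))
  expect_identical(predict(cl, x), predict(cl, x))
  # smoothed training loss decreases
  sm <- stats::filter(cl$training_log, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_error(train_attention_classifier(x, rep("a", 80), cfg, type = "features"),
               "two distinct")
})

test_that("1-D and 2-D views train through the same architecture", {
  set.seed(11)
  n <- 24
  spectra <- rbind(matrix(rnorm(n / 2 * 64, 0), n / 2, 64),
                   matrix(rnorm(n / 2 * 64, 2), n / 2, 64))
  y <- rep(c("a", "b"), each = n / 2)
  cfg <- attention_config(embed_dim = 8, n_heads = 2, depth = 1,
                          mlp_hidden = 16, patch_size_1d = 16,
                          patch_size_2d = c(4, 8), epochs = 40,
                          learning_rate = 5e-3, seed = 3)
  cl1 <- train_attention_classifier(spectra, y, cfg)
  expect_equal(cl1$kind, "ATTENTION_1D")
  expect_gt(mean(predict(cl1, spectra, type = "class") == y), 0.9)
  mats <- lapply(seq_len(n), function(i) matrix(spectra[i, ], 8, 8))
  cl2 <- train_attention_classifier(mats, y, cfg)
  expect_equal(cl2$kind, "ATTENTION_2D")
  expect_gt(mean(predict(cl2, mats, type = "class") == y), 0.9)
})

test_that("baselines expose the shared probability contract", {
  set.seed(13)
  x <- rbind(matrix(rnorm(30 * 4, 0), 30, 4), matrix(rnorm(30 * 4, 2.5), 30, 4))
  y <- rep(c("0", "100"), each = 30)
  knn <- train_baseline(x, y, "KNN", list(k = 1))
  expect_equal(mean(predict(knn, x, type = "class") == y), 1)  # k = 1 memorises
  pk <- predict(knn, x, type = "prob")
  expect_equal(rowSums(pk), rep(1, 60))

  rf1 <- train_baseline(x, y, "RF", seed = 5)
  rf2 <- train_baseline(x, y, "RF", seed = 5)
  expect_identical(predict(rf1, x), predict(rf2, x))
  pr <- predict(rf1, x, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 60), tolerance = 1e-9)
  expect_error(train_baseline(x, rep("0", 60), "KNN"), "two distinct")
})
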