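test_that("stratified splitting hits the per-class arithmetic exactly", {
  labels <- rep(c(0, 10, 100), each = 24)  # 72 samples, 24 per class
  sp <- split_dataset(labels, ratios = c(2 / 3, 1 / 3), k_folds = 4, seed = 9)
  expect_length(sp$calibration, 48)
  expect_length(sp$validation, 24)
  y <- factor(labels)
  expect_true(all(table(y[sp$calibration]) == 16))
  expect_true(all(table(y[sp$validation]) == 8))
  # disjoint and exhaustive
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), seq_along(labels))
  # folds stratified inside calibration
  expect_true(all(table(sp$folds, y[sp$calibration]) == 4))
  # determinism
  sp2 <- split_dataset(labels, ratios = c(2 / 3, 1 / 3), k_folds = 4, seed = 9)
  expect_identical(sp, sp2)
  expect_false(identical(sp$calibration,
                         split_dataset(labels, k_folds = 4, seed = 10)$calibration))
})

test_that("degenerate split requests warn or error as appropriate", {
  labels <- rep(c("a", "b"), each = 10)
  expect_warning(split_dataset(labels, ratios = c(1, 0), k_folds = 2), "empty")
  expect_error(split_dataset(labels, ratios = c(0.5, 0.4)), "sum to 1")
  expect_error(split_dataset(labels, k_folds = 50), "fewer than")
})

test_that("confusion counts land by (true, predicted) cell", {
  cls <- c("0", "10", "100")
  truth <- rep(cls, each = 24)
  cm <- confusion(truth, truth, cls)
  expect_equal(unname(diag(cm)), c(24, 24, 24))
  expect_equal(sum(cm), 72)

  all0 <- confusion(truth, rep("0", 72), cls)
  expect_equal(unname(all0[, 1]), c(24, 24, 24))
  expect_equal(sum(all0[, 2:3]), 0)

  empty <- confusion(character(0), character(0), cls)
  expect_true(all(empty == 0))
  expect_error(confusion(truth, c(rep("0", 71), "bad"), cls), "bad")
  expect_error(confusion("0", c("0", "10"), cls), "equal length")
})

test_that("one-vs-rest metrics reproduce the worked three-class matrices", {
  cls <- c("0", "10", "100")
  mk <- function(rows) {
    cm <- matrix(as.integer(t(rows)), 3, 3, byrow = FALSE,
                 dimnames = list(true = cls, predicted = cls))
    cm <- t(cm)  # rows = true
    class(cm) <- c("confusion_matrix", class(cm))
    class_metrics(cm)
  }
  # PET task: one control sample predicted as 10 mg/L
  pet <- mk(rbind(c(23, 1, 0), c(0, 24, 0), c(0, 0, 24)))
  expect_equal(round(pet$accuracy, 2), 98.61)
  expect_equal(round(unname(pet$sensitivity["0"]), 2), 95.83)
  expect_equal(unname(pet$sensitivity[c("10", "100")]), c(100, 100))
  expect_equal(round(unname(pet$specificity["10"]), 2), 97.92)
  expect_equal(unname(pet$specificity[c("0", "100")]), c(100, 100))

  # PS task: six samples leak into the 100 mg/L column
  ps <- mk(rbind(c(21, 0, 3), c(0, 21, 3), c(0, 0, 24)))
  expect_equal(round(ps$accuracy, 2), 91.67)
  expect_equal(unname(ps$sensitivity[c("0", "10", "100")]), c(87.5, 87.5, 100))
  expect_equal(unname(ps$specificity[c("0", "10", "100")]), c(100, 100, 87.5))

  # PVC task: two control samples predicted as 10 mg/L
  pvc <- mk(rbind(c(22, 2, 0), c(0, 24, 0), c(0, 0, 24)))
  expect_equal(round(pvc$accuracy, 2), 97.22)
  expect_equal(round(unname(pvc$sensitivity["0"]), 2), 91.67)
  expect_equal(round(unname(pvc$specificity["10"]), 2), 95.83)
  expect_equal(unname(pvc$specificity[c("0", "100")]), c(100, 100))

  # perfect classification: everything 100
  perfect <- mk(diag(3) * 24)
  expect_equal(perfect$accuracy, 100)
  expect_equal(unname(perfect$sensitivity), rep(100, 3))
  expect_equal(unname(perfect$specificity), rep(100, 3))
})

test_that("accuracy equals the prior-weighted mean of sensitivities", {
  set.seed(21)
  for (rep in 1:5) {
    cm <- confusion(sample(c("a", "b", "c"), 60, TRUE),
                    sample(c("a", "b", "c"), 60, TRUE), c("a", "b", "c"))
    m <- class_metrics(cm)
    priors <- rowSums(cm) / sum(cm)
    expect_equal(m$accuracy, sum(priors * m$sensitivity), tolerance = 1e-9)
  }
  # empty true row flags NA sensitivity but computes the rest
  cm0 <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b", "c"))
  m0 <- class_metrics(cm0)
  expect_true(is.na(m0$sensitivity["c"]))
  expect_false(anyNA(m0$specificity))
})

test_that("the excitation sweep finds the discriminative wavelength", {
  # only the fulvic-like component (excited at 360 nm) responds to dose
  cat5 <- default_fluorophore_catalog()
  gen <- generate_eem_dataset(
    effects = default_treatment_effects(cat5, affected_components = "C4_fulvic"),
    noise = noise_model(additive_gaussian_sigma = 5),
    n_per_group = 6, seed = 33)
  pp <- preprocess_dataset(gen$dataset)
  cfg <- attention_config(embed_dim = 16, n_heads = 2, depth = 1,
                          mlp_hidden = 32, patch_size_1d = 32, epochs = 120,
                          learning_rate = 5e-3, batch_size = 14, seed = 4)
  ex_list <- seq(260, 460, by = 50)
  curve <- excitation_sweep(pp, cfg, ex_list, seed = 6)
  expect_equal(curve$ex_nm, ex_list)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 100))
  best <- curve$ex_nm[which.max(curve$accuracy)]
  expect_lte(abs(best - 360), 25)
})

test_that("shuffled labels drive sweep accuracy to chance", {
  pp <- get_small_pp()
  shuffled <- pp
  # class labels live in the manifest as far as the sweep is concerned
  shuffled$manifest$concentration <- with_seed(91, sample(pp$manifest$concentration))
  cfg <- attention_config(embed_dim = 8, n_heads = 2, depth = 1,
                          mlp_hidden = 16, patch_size_1d = 64, epochs = 25,
                          learning_rate = 5e-3, batch_size = 19, seed = 4)
  curve <- excitation_sweep(shuffled, cfg, c(300, 350, 400, 450), seed = 6)
  expect_gt(mean(curve$accuracy), 33.3 - 10)
  expect_lt(mean(curve$accuracy), 33.3 + 10)
})
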