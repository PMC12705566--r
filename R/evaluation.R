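#' Stratified calibration / validation split with CV folds
#'
#' Splits sample indices into a calibration and a validation partition,
#' stratified by class, and assigns k cross-validation folds (also
#' stratified) within the calibration partition. Deterministic given the
#' seed; the partitions are disjoint and exhaustive.
#'
#' @param labels Class label per sample.
#' @param ratios Numeric `(calibration, validation)` summing to 1
#'   (default 2/3 calibration, 1/3 validation).
#' @param k_folds CV folds inside the calibration set (default 5).
#' @param seed Integer seed.
#' @return List with integer index vectors `calibration`, `validation`,
#'   and `folds` (fold id per calibration sample, parallel to
#'   `calibration`).
#' @export
split_dataset <- function(labels, ratios = c(2 / 3, 1 / 3), k_folds = 5,
                          seed = 1) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1", call. = FALSE)
  y <- as_class_factor(labels)
  n <- length(y)
  cal <- integer(0); val <- integer(0)
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      n_cal <- round(length(idx) * ratios[1])
      cal <- c(cal, idx[seq_len(n_cal)])
      if (n_cal < length(idx)) val <- c(val, idx[(n_cal + 1):length(idx)])
    }
    cal <- sort(cal); val <- sort(val)
    if (length(val) == 0) warning("validation partition is empty")
    folds <- integer(length(cal))
    for (cls in levels(y)) {
      in_cls <- which(y[cal] == cls)
      if (length(in_cls) < k_folds) {
        stop(sprintf("class %s has %d calibration samples, fewer than %d folds",
                     cls, length(in_cls), k_folds), call. = FALSE)
      }
      folds[sample(in_cls)] <- rep_len(seq_len(k_folds), length(in_cls))
    }
    list(calibration = cal, validation = val, folds = folds)
  })
}

#' Confusion matrix over an ordered class set
#'
#' @param true,predicted Equal-length label vectors.
#' @param class_order Ordered class levels (rows = true, columns =
#'   predicted); any label outside this set is an error.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true, predicted, class_order = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (is.null(class_order)) class_order <- levels(as_class_factor(true))
  class_order <- as.character(class_order)
  bad <- setdiff(unique(c(true, predicted)), class_order)
  if (length(bad)) {
    stop(sprintf("label outside class_order: %s", bad[1]), call. = FALSE)
  }
  cm <- table(factor(true, levels = class_order),
              factor(predicted, levels = class_order))
  m <- matrix(as.integer(cm), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(matrix(unclass(x), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' One-vs-rest sensitivity/specificity and overall accuracy
#'
#' For class c: sensitivity is the true-positive rate within row c
#' (`100 * TP / row total`); specificity is the true-negative rate among
#' samples not in c, with false positives counted column-wise
#' (`100 * TN / (TN + FP)`, `FP` = off-row counts in column c); accuracy is
#' `100 * trace / total`. A class with an empty true row gets `NA`
#' sensitivity while the remaining metrics are still computed.
#'
#' @param cm A [confusion()] matrix.
#' @return List of class `class_metrics`: `sensitivity`, `specificity`
#'   (named per class, percent), `accuracy` (percent).
#' @export
class_metrics <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  classes <- rownames(m)
  sens <- spec <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_along(classes)) {
    row_total <- sum(m[i, ])
    sens[i] <- if (row_total == 0) NA_real_ else 100 * m[i, i] / row_total
    fp <- sum(m[-i, i])
    tn <- sum(m[-i, ]) - fp
    spec[i] <- 100 * tn / (tn + fp)
  }
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = 100 * sum(diag(m)) / total),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %.2f%%\n", x$accuracy))
  for (cls in names(x$sensitivity)) {
    cat(sprintf("  class %s: sensitivity %.2f%%, specificity %.2f%%\n",
                cls, x$sensitivity[cls], x$specificity[cls]))
  }
  invisible(x)
}

#' Fit, predict and score one classifier on a labelled split
#'
#' Convenience wrapper used by the pipeline: trains on the calibration
#' rows, predicts the validation rows, and returns the confusion matrix
#' and metrics.
#'
#' @param features Feature matrix (rows = samples).
#' @param labels Class label per sample.
#' @param split A [split_dataset()] result.
#' @param trainer Function `(features, labels) -> classifier`.
#' @return List with `model`, `confusion`, `metrics`, `predicted`.
#' @export
evaluate_classifier <- function(features, labels, split, trainer) {
  y <- droplevels(as_class_factor(labels))
  model <- trainer(features[split$calibration, , drop = FALSE],
                   y[split$calibration])
  pred <- predict(model, features[split$validation, , drop = FALSE],
                  type = "class")
  cm <- confusion(as.character(y[split$validation]), pred, levels(y))
  list(model = model, confusion = cm, metrics = class_metrics(cm),
       predicted = pred)
}

#' Per-excitation-wavelength classification sweep
#'
#' For every requested excitation wavelength, trains the 1-D attention
#' classifier on that wavelength's emission slices and records validation
#' accuracy — locating the excitation wavelengths that carry the most
#' class information.
#'
#' @param dataset Preprocessed `eem_dataset` (typically one polymer plus
#'   its control).
#' @param config An [attention_config()].
#' @param ex_list Excitation wavelengths (on the grid).
#' @param ratios,seed Passed to [split_dataset()].
#' @return Data frame `(ex_nm, accuracy)` ordered as `ex_list`.
#' @export
excitation_sweep <- function(dataset, config = attention_config(),
                             ex_list = dataset$grid$ex,
                             ratios = c(2 / 3, 1 / 3), seed = 1) {
  stopifnot(inherits(dataset, "eem_dataset"))
  labels <- as_class_factor(dataset$manifest$concentration)
  k_folds <- max(2, min(5, floor(min(table(labels)) * ratios[1])))
  split <- split_dataset(labels, ratios = ratios, k_folds = k_folds, seed = seed)
  acc <- numeric(length(ex_list))
  for (i in seq_along(ex_list)) {
    slices <- t(vapply(dataset$samples, extract_emission_slice,
                       numeric(dataset$grid$n_em), ex_nm = ex_list[i]))
    res <- evaluate_classifier(
      slices, labels, split,
      function(x, y) train_attention_classifier(x, y, config))
    acc[i] <- res$metrics$accuracy
  }
  data.frame(ex_nm = ex_list, accuracy = acc)
}
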