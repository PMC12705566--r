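#' Train a KNN or random-forest baseline classifier
#'
#' Both baselines expose the same probability-vector prediction contract as
#' the attention classifier (one row per sample, summing to 1 over the
#' ordered class levels). Full EEMs are unfolded to vectors by the caller
#' before entering either baseline. The KNN vote distribution is computed
#' directly from the Euclidean distance matrix (vote fractions over the k
#' nearest training samples); the random forest wraps
#' [randomForest::randomForest()].
#'
#' @param features `n x p` numeric feature matrix.
#' @param labels Class labels, one per row.
#' @param kind `"KNN"` or `"RF"`.
#' @param hyperparams List: `k` (KNN neighbours, default 5), `ntree`
#'   (RF trees, default 500).
#' @param seed Integer seed (RF bootstrap; KNN is deterministic anyway).
#' @return An object of class `baseline_classifier` (also
#'   `eem_classifier`).
#' @export
train_baseline <- function(features, labels, kind = c("KNN", "RF"),
                           hyperparams = list(), seed = 1) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  y <- droplevels(as_class_factor(labels))
  if (nlevels(y) < 2) stop("training requires at least two distinct classes", call. = FALSE)
  fit <- if (kind == "KNN") {
    list(x = features, y = y, k = hyperparams$k %||% 5)
  } else {
    with_seed(seed, {
      randomForest::randomForest(x = features, y = y,
                                 ntree = hyperparams$ntree %||% 500)
    })
  }
  structure(list(kind = kind, fit = fit, classes = levels(y), seed = seed),
            class = c("baseline_classifier", "eem_classifier"))
}

#' @rdname train_baseline
#' @param object A `baseline_classifier`.
#' @param newdata Feature matrix with the training column layout.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.baseline_classifier <- function(object, newdata,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  probs <- if (object$kind == "KNN") {
    tr <- object$fit
    k <- min(tr$k, nrow(tr$x))
    t(apply(newdata, 1, function(v) {
      d <- sqrt(colSums((t(tr$x) - v)^2))
      nn <- order(d)[seq_len(k)]
      tabulate(as.integer(tr$y[nn]), nbins = nlevels(tr$y)) / k
    }))
  } else {
    unclass(stats::predict(object$fit, newdata, type = "prob"))
  }
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.baseline_classifier <- function(x, ...) {
  cat(sprintf("<baseline_classifier> %s; classes: %s\n", x$kind,
              paste(x$classes, collapse = "/")))
  invisible(x)
}
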