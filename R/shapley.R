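#' Scalar model-output function for one class probability
#'
#' Shapley attribution explains a scalar model output; for classifiers the
#' package explains the predicted probability of a chosen class
#' (interpretable on the 0-1 scale). This helper adapts any fitted
#' `eem_classifier` to the `f(feature_matrix) -> numeric` contract the
#' Shapley functions expect.
#'
#' @param model A fitted classifier with a probability `predict` method.
#' @param class Class label whose probability is explained.
#' @return Function mapping an `n x p` feature matrix to a length-n
#'   numeric vector.
#' @export
class_prob_fn <- function(model, class) {
  class <- as.character(class)
  if (!class %in% model$classes) {
    stop(sprintf("unknown class %s; model classes are %s", class,
                 paste(model$classes, collapse = ", ")), call. = FALSE)
  }
  if (inherits(model, "attention_classifier")) {
    function(x) predict(model, x, type = "prob")[, class]
  } else {
    function(x) predict(model, x, type = "prob")[, class]
  }
}

#' Masked model evaluation (SHAP-style value function)
#'
#' Evaluates the model on the explained instance with every feature
#' outside `subset` replaced by its background (calibration-set mean)
#' value — the coalition value `v(S)` of the Shapley game.
#'
#' @param f Scalar model function (see [class_prob_fn()]).
#' @param instance Numeric feature vector being explained.
#' @param subset Integer indices or feature names present in the
#'   coalition (empty = all background).
#' @param background Numeric vector of background feature values
#'   (same length/names as `instance`).
#' @return Scalar model output.
#' @export
value_function <- function(f, instance, subset, background) {
  instance <- unlist(instance)
  background <- unlist(background)
  p <- length(instance)
  if (is.character(subset)) {
    miss <- setdiff(subset, names(instance))
    if (length(miss)) stop(sprintf("unknown feature: %s", miss[1]), call. = FALSE)
    subset <- match(subset, names(instance))
  }
  if (length(subset) && (any(subset < 1) || any(subset > p))) {
    stop("subset references unknown feature index", call. = FALSE)
  }
  x <- background
  x[subset] <- instance[subset]
  m <- matrix(x, nrow = 1, dimnames = list(NULL, names(instance)))
  as.numeric(f(m))
}

masked_matrix <- function(masks, instance, background) {
  out <- matrix(background, nrow = nrow(masks), ncol = length(instance),
                byrow = TRUE)
  out[masks] <- matrix(instance, nrow = nrow(masks), ncol = length(instance),
                       byrow = TRUE)[masks]
  colnames(out) <- names(instance)
  out
}

#' Exact Shapley attribution by coalition enumeration
#'
#' Computes `phi_i = sum over S not containing i of
#' |S|! (p - |S| - 1)! / p! * (v(S + i) - v(S))` over all `2^p` coalitions.
#' Satisfies the efficiency axiom exactly:
#' `base_value + sum(phi) = f(instance)`.
#'
#' @param f Scalar model function.
#' @param instance Named numeric feature vector (`p <= 15`).
#' @param background Background feature vector (calibration means).
#' @return An object of class `eem_attribution`: `phi` (named), `base_value`
#'   (`f(background)`), `fx` (`f(instance)`), `method = "exact"`.
#' @export
exact_shapley <- function(f, instance, background) {
  instance <- unlist(instance)
  background <- unlist(background)
  p <- length(instance)
  if (p > 15) {
    stop("p > 15: exact enumeration is infeasible, use sampled_shapley()", call. = FALSE)
  }
  n_sub <- 2L^p
  masks <- matrix(FALSE, n_sub, p)
  for (i in seq_len(p)) masks[, i] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, i - 1L)) > 0
  v <- as.numeric(f(masked_matrix(masks, instance, background)))
  sizes <- rowSums(masks)
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  phi <- stats::setNames(numeric(p), names(instance))
  idx <- seq_len(n_sub)
  for (i in seq_len(p)) {
    without <- idx[!masks[, i]]
    with_i <- without + bitwShiftL(1L, i - 1L)
    phi[i] <- sum(wts[sizes[without] + 1] * (v[with_i] - v[without]))
  }
  structure(list(phi = phi, base_value = v[1], fx = v[n_sub],
                 method = "exact", se = NULL),
            class = "eem_attribution")
}

#' Monte-Carlo (permutation) Shapley attribution
#'
#' Averages marginal contributions over random feature orderings. Each
#' permutation telescopes from `v(empty)` to `v(full)`, so efficiency
#' holds for the averaged estimate as well. Per-feature Monte-Carlo
#' standard errors are reported.
#'
#' @param f Scalar model function.
#' @param instance Named numeric feature vector (any length).
#' @param background Background feature vector.
#' @param n_permutations Number of random orderings (`>= 1`).
#' @param seed Integer seed; the estimate is deterministic given the seed.
#' @return An `eem_attribution` with `method = "sampled"` and `se`.
#' @export
sampled_shapley <- function(f, instance, background, n_permutations = 200,
                            seed = 1) {
  instance <- unlist(instance)
  background <- unlist(background)
  p <- length(instance)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  contrib <- matrix(0, n_permutations, p)
  base <- as.numeric(f(matrix(background, nrow = 1,
                              dimnames = list(NULL, names(instance)))))
  with_seed(seed, {
    for (r in seq_len(n_permutations)) {
      ord <- sample.int(p)
      masks <- matrix(FALSE, p + 1, p)
      for (s in seq_len(p)) masks[s + 1, ord[seq_len(s)]] <- TRUE
      v <- as.numeric(f(masked_matrix(masks, instance, background)))
      contrib[r, ord] <- diff(v)
    }
  })
  phi <- stats::setNames(colMeans(contrib), names(instance))
  se <- if (n_permutations > 1) apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  else rep(NA_real_, p)
  structure(list(phi = phi, base_value = base, fx = base + sum(phi),
                 method = "sampled", se = stats::setNames(se, names(instance))),
            class = "eem_attribution")
}

#' @export
print.eem_attribution <- function(x, ...) {
  cat(sprintf("<eem_attribution> (%s) base %.4g -> f(x) %.4g\n",
              x$method, x$base_value, x$fx))
  print(round(x$phi, 5))
  invisible(x)
}

#' Ranked mean-|phi| importance summary
#'
#' Aggregates per-instance attributions into mean absolute Shapley value
#' per feature, overall and conditioned on the true class, with stable
#' ranking (ties broken by feature catalog order).
#'
#' @param attributions List of `eem_attribution` objects (one per
#'   explained sample).
#' @param true_classes Optional class label per attribution; when given,
#'   per-class summaries are appended.
#' @return Data frame `(feature, class, mean_abs_shap, rank)`; `class` is
#'   `"overall"` or a class level.
#' @export
importance_summary <- function(attributions, true_classes = NULL) {
  if (length(attributions) == 0) stop("need at least one attribution", call. = FALSE)
  phi <- t(vapply(attributions, `[[`, attributions[[1]]$phi, "phi"))
  features <- colnames(phi)
  one_block <- function(rows, cls) {
    mabs <- colMeans(abs(phi[rows, , drop = FALSE]))
    rk <- rank(-mabs, ties.method = "first")
    data.frame(feature = features, class = cls, mean_abs_shap = mabs,
               rank = rk, row.names = NULL)
  }
  out <- one_block(seq_len(nrow(phi)), "overall")
  if (!is.null(true_classes)) {
    y <- as_class_factor(true_classes)
    for (cls in levels(y)) {
      out <- rbind(out, one_block(which(y == cls), cls))
    }
  }
  out
}
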