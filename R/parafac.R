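# --- tensor utilities ------------------------------------------------------

# Column-wise Khatri-Rao product: KR[, f] = kron(M[, f], N[, f]).
khatri_rao <- function(M, N) {
  M[rep(seq_len(nrow(M)), each = nrow(N)), , drop = FALSE] *
    N[rep(seq_len(nrow(N)), times = nrow(M)), , drop = FALSE]
}

#' Compose a trilinear (CP) tensor from factor matrices
#'
#' `X[i, j, k] = sum_f A[i, f] * B[j, f] * C[k, f]` — the PARAFAC model
#' equation, used both by the synthetic generator and to reconstruct fitted
#' models.
#'
#' @param A,B,C Factor matrices with a common number of columns.
#' @return A 3-way array of dimension `nrow(A) x nrow(B) x nrow(C)`.
#' @export
cp_compose <- function(A, B, C) {
  array(A %*% t(khatri_rao(C, B)), dim = c(nrow(A), nrow(B), nrow(C)))
}

# Mode-n unfoldings matching khatri_rao() column ordering.
unfold1 <- function(X) matrix(X, dim(X)[1])
unfold2 <- function(X) matrix(aperm(X, c(2, 1, 3)), dim(X)[2])
unfold3 <- function(X) matrix(aperm(X, c(3, 1, 2)), dim(X)[3])

#' Stack an EEM dataset into a sample x excitation x emission tensor
#'
#' @param dataset An `eem_dataset` of preprocessed (NA-free) samples.
#' @param decimate_em Keep every `decimate_em`-th emission wavelength
#'   (1 = keep all). Decimation shrinks the fit without moving component
#'   positions.
#' @return 3-way array with attributes `ex` and `em` (the wavelength axes)
#'   and `sample_id`.
#' @export
dataset_tensor <- function(dataset, decimate_em = 1) {
  stopifnot(inherits(dataset, "eem_dataset"), length(dataset$samples) > 0)
  keep <- seq(1, dataset$grid$n_em, by = decimate_em)
  n <- length(dataset$samples)
  X <- array(0, dim = c(n, dataset$grid$n_ex, length(keep)))
  for (i in seq_len(n)) {
    X[i, , ] <- dataset$samples[[i]]$intensities[, keep, drop = FALSE]
  }
  attr(X, "ex") <- dataset$grid$ex
  attr(X, "em") <- dataset$grid$em[keep]
  attr(X, "sample_id") <- dataset$manifest$sample_id
  X
}

#' Tucker congruence (cosine similarity) between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sum(x * y) / sqrt(sum(x^2) * sum(y^2))`; 1 for identical shapes
#'   up to positive scale.
#' @export
tucker_congruence <- function(x, y) {
  d <- sqrt(sum(x^2) * sum(y^2))
  if (d == 0) return(0)
  sum(x * y) / d
}

# Greedy one-to-one matching of columns of (ex1|em1) against (ex2|em2) by
# Tucker congruence on the concatenated loading vectors. Returns a data
# frame (component of model 1, matched component of model 2, congruence).
match_components <- function(ex1, em1, ex2, em2) {
  F <- ncol(ex1)
  cong <- matrix(0, F, F)
  for (i in seq_len(F)) {
    for (j in seq_len(F)) {
      cong[i, j] <- tucker_congruence(c(ex1[, i], em1[, i]), c(ex2[, j], em2[, j]))
    }
  }
  pairs <- data.frame(from = integer(F), to = integer(F), congruence = numeric(F))
  left <- seq_len(F)
  right <- seq_len(F)
  for (k in seq_len(F)) {
    sub <- cong[left, right, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pairs$from[k] <- left[best[1]]
    pairs$to[k] <- right[best[2]]
    pairs$congruence[k] <- sub[best[1], best[2]]
    left <- left[-best[1]]
    right <- right[-best[2]]
  }
  pairs[order(pairs$from), ]
}

# --- nonnegative CP-ALS (HALS) --------------------------------------------

# One HALS sweep over the columns of factor `A` for unfolding product
# P = X(n) %*% KR and gram Q = hadamard of the other two factor grams.
hals_update <- function(A, P, Q) {
  for (f in seq_len(ncol(A))) {
    qff <- Q[f, f]
    if (qff < 1e-12) next
    a <- A[, f] + (P[, f] - A %*% Q[, f]) / qff
    a[a < 0] <- 0
    if (all(a == 0)) a <- rep(1e-12, length(a))
    A[, f] <- a
  }
  A
}

fit_parafac_once <- function(X1, X2, X3, dims, F, tol, max_iter, normX2) {
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  A <- matrix(stats::runif(n1 * F, 0.1, 1), n1, F)
  B <- matrix(stats::runif(n2 * F, 0.1, 1), n2, F)
  C <- matrix(stats::runif(n3 * F, 0.1, 1), n3, F)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    A <- hals_update(A, X1 %*% khatri_rao(C, B), crossprod(B) * crossprod(C))
    B <- hals_update(B, X2 %*% khatri_rao(C, A), crossprod(A) * crossprod(C))
    C <- hals_update(C, X3 %*% khatri_rao(B, A), crossprod(A) * crossprod(B))
    # residual fraction ||X - Xhat||^2 / ||X||^2 via gram identities
    P1 <- X1 %*% khatri_rao(C, B)
    gram <- crossprod(A) * crossprod(B) * crossprod(C)
    err <- max(0, (normX2 - 2 * sum(A * P1) + sum(gram)) / normX2)
    trace <- c(trace, err)
    if (is.finite(prev) && abs(prev - err) < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- err
  }
  # absorb scale into A; unit-norm spectral loadings
  nb <- sqrt(colSums(B^2)); nb[nb == 0] <- 1
  nc <- sqrt(colSums(C^2)); nc[nc == 0] <- 1
  list(A = sweep(A, 2, nb * nc, "*"),
       B = sweep(B, 2, nb, "/"),
       C = sweep(C, 2, nc, "/"),
       fit_error = trace[length(trace)], trace = trace,
       n_iterations = it, converged = converged)
}

#' Fit a nonnegative PARAFAC (CP) model to an EEM tensor
#'
#' Alternating least squares with non-negativity on all three modes
#' (fluorescence scores and spectra are physically non-negative), using
#' HALS column updates, which decrease the residual sum of squares at every
#' sweep. The best of `n_restarts` random initialisations by final fit
#' error is returned. Scale indeterminacy is resolved by unit-norm
#' excitation/emission loading columns with the magnitude absorbed into the
#' sample scores.
#'
#' @param X 3-way array (sample x excitation x emission), no missing or
#'   non-finite values; typically from [dataset_tensor()].
#' @param F Number of components, `1 <= F <= min(dim(X))`.
#' @param n_restarts Random initialisations.
#' @param tol Convergence tolerance on the relative change of the residual
#'   fraction.
#' @param max_iter Maximum ALS sweeps per restart.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return An object of class `parafac_model`: `sample_scores`
#'   (n x F, >= 0), `ex_loadings` / `em_loadings` (unit-norm columns,
#'   >= 0), `fit_error` (residual sum-of-squares fraction in `[0, 1]`),
#'   `fit_trace`, `n_iterations`, `converged`, and the wavelength axes when
#'   present on `X`.
#' @export
fit_parafac <- function(X, F, n_restarts = 10, tol = 1e-8, max_iter = 500,
                        seed = 1) {
  if (!is.array(X) || length(dim(X)) != 3) stop("X must be a 3-way array", call. = FALSE)
  if (any(!is.finite(X))) stop("X contains non-finite values; preprocess first", call. = FALSE)
  F <- as.integer(F)
  if (F < 1 || F > min(dim(X))) {
    stop(sprintf("rank F = %d outside 1..min(dim) = %d", F, min(dim(X))), call. = FALSE)
  }
  dims <- dim(X)
  X1 <- unfold1(X); X2 <- unfold2(X); X3 <- unfold3(X)
  normX2 <- sum(X^2)
  if (normX2 == 0) stop("X is identically zero", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + (r - 1), {
      fit_parafac_once(X1, X2, X3, dims, F, tol, max_iter, normX2)
    })
    if (is.null(best) || fit$fit_error < best$fit_error) best <- fit
  }
  structure(
    list(n_components = F,
         sample_scores = best$A,
         ex_loadings = best$B,
         em_loadings = best$C,
         fit_error = best$fit_error,
         fit_trace = best$trace,
         n_iterations = best$n_iterations,
         converged = best$converged,
         ex = attr(X, "ex"), em = attr(X, "em")),
    class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("<parafac_model> F = %d, fit_error = %.3g, %d iterations%s\n",
              x$n_components, x$fit_error, x$n_iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

# least-squares Tucker core for fixed factors, via mode products with
# pseudo-inverses (valid because the LS problem separates over modes).
ls_tucker_core <- function(X, A, B, C) {
  F <- ncol(A)
  G1 <- pracma::pinv(A) %*% unfold1(X)                       # F x (n2 n3)
  G <- array(G1, dim = c(F, dim(X)[2], dim(X)[3]))
  G2 <- pracma::pinv(B) %*% unfold2(G)
  G <- aperm(array(G2, dim = c(F, F, dim(X)[3])), c(2, 1, 3))
  G3 <- pracma::pinv(C) %*% unfold3(G)
  aperm(array(G3, dim = c(F, F, F)), c(2, 3, 1))
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Fits the least-squares Tucker core `G` for the model's fixed loadings
#' and compares it to the superdiagonal identity core `T` that an ideal
#' trilinear model implies: `100 * (1 - sum((G - T)^2) / sum(T^2))`. Values
#' near 100 support the chosen rank; over-factored models collapse towards
#' (or below) 0.
#'
#' @param model A `parafac_model`.
#' @param X The tensor the model was fitted to.
#' @return Core consistency percentage (`<= 100`, possibly negative), with
#'   attribute `degenerate = TRUE` (value `NA`) when a factor matrix is
#'   rank-deficient so the diagnostic is meaningless.
#' @export
core_consistency <- function(model, X) {
  stopifnot(inherits(model, "parafac_model"))
  A <- model$sample_scores; B <- model$ex_loadings; C <- model$em_loadings
  F <- model$n_components
  if (qr(A)$rank < F || qr(B)$rank < F || qr(C)$rank < F) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  G <- ls_tucker_core(X, A, B, C)
  Tcore <- array(0, dim = c(F, F, F))
  for (f in seq_len(F)) Tcore[f, f, f] <- 1
  structure(100 * (1 - sum((G - Tcore)^2) / F), degenerate = FALSE)
}

#' Split-half validation of a PARAFAC rank
#'
#' Randomly halves the samples, fits both halves at rank `F`, greedily
#' matches components across halves by Tucker congruence on the
#' concatenated excitation+emission loadings, and scores the split as
#' 100 x mean matched congruence. The reported similarity is the worst
#' split over `n_splits` random splits — a stable decomposition must
#' survive every split.
#'
#' @param X Sample x excitation x emission tensor with at least 4 samples.
#' @param F Candidate rank.
#' @param n_splits Number of random splits.
#' @param seed Integer seed (controls splits and fits).
#' @param n_restarts,tol,max_iter Passed to [fit_parafac()] for the half
#'   fits (fewer restarts than a final fit: each half is fitted
#'   `2 * n_splits` times).
#' @return Similarity percent (worst split), with attribute `per_split`.
#' @export
split_half <- function(X, F, n_splits = 3, seed = 1, n_restarts = 3,
                       tol = 1e-8, max_iter = 500) {
  n <- dim(X)[1]
  if (n < 4) stop("split-half analysis needs at least 4 samples", call. = FALSE)
  sims <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    perm <- with_seed(seed + 1000 * s, sample.int(n))
    h1 <- sort(perm[seq_len(n %/% 2)])
    h2 <- sort(perm[(n %/% 2 + 1):n])
    m1 <- fit_parafac(X[h1, , , drop = FALSE], F, n_restarts = n_restarts,
                      tol = tol, max_iter = max_iter, seed = seed + 7 * s)
    m2 <- fit_parafac(X[h2, , , drop = FALSE], F, n_restarts = n_restarts,
                      tol = tol, max_iter = max_iter, seed = seed + 7 * s + 3)
    pairs <- match_components(m1$ex_loadings, m1$em_loadings,
                              m2$ex_loadings, m2$em_loadings)
    sims[s] <- 100 * mean(pairs$congruence)
  }
  structure(min(sims), per_split = sims)
}

#' Rank selection by split-half similarity and core consistency
#'
#' Computes fit error, core consistency and split-half similarity for every
#' candidate rank and chooses the largest rank whose split-half similarity
#' reaches `split_threshold` and whose core consistency reaches
#' `cc_threshold` — the most detailed model that is still stable and still
#' trilinear-consistent.
#'
#' @param X Sample x excitation x emission tensor.
#' @param F_range Candidate ranks (e.g. `3:6`).
#' @param split_threshold Minimum admissible split-half similarity, percent.
#' @param cc_threshold Minimum admissible core consistency, percent.
#' @param seed Integer seed.
#' @param n_restarts,n_splits,tol,max_iter Passed through to the fits.
#' @return List with `diagnostics` (data frame: F, fit_error,
#'   core_consistency, split_half_similarity), `chosen` (selected rank) and
#'   `admissible_empty` (TRUE when no rank met both thresholds and the
#'   smallest candidate was returned with a warning).
#' @export
select_rank <- function(X, F_range = 3:6, split_threshold = 95,
                        cc_threshold = 60, seed = 1, n_restarts = 3,
                        n_splits = 3, tol = 1e-8, max_iter = 500) {
  if (length(F_range) == 0) stop("F_range must be non-empty", call. = FALSE)
  F_range <- sort(unique(as.integer(F_range)))
  diag <- data.frame(F = F_range, fit_error = NA_real_,
                     core_consistency = NA_real_,
                     split_half_similarity = NA_real_)
  for (i in seq_along(F_range)) {
    F <- F_range[i]
    m <- fit_parafac(X, F, n_restarts = n_restarts, tol = tol,
                     max_iter = max_iter, seed = seed)
    diag$fit_error[i] <- m$fit_error
    diag$core_consistency[i] <- as.numeric(core_consistency(m, X))
    diag$split_half_similarity[i] <- as.numeric(
      split_half(X, F, n_splits = n_splits, seed = seed,
                 n_restarts = n_restarts, tol = tol, max_iter = max_iter))
  }
  ok <- !is.na(diag$core_consistency) &
    diag$split_half_similarity >= split_threshold &
    diag$core_consistency >= cc_threshold
  if (any(ok)) {
    chosen <- max(diag$F[ok])
    empty <- FALSE
  } else {
    chosen <- min(diag$F)
    empty <- TRUE
    warning("no candidate rank met both thresholds; returning the smallest candidate")
  }
  list(diagnostics = diag, chosen = chosen, admissible_empty = empty)
}

#' Project new samples onto fitted PARAFAC loadings
#'
#' Featurises held-out samples without refitting: each sample's unfolded
#' EEM is regressed (non-negative least squares) onto the Khatri-Rao
#' structure of the fixed excitation/emission loadings.
#'
#' @param model A `parafac_model`.
#' @param newdata An `eem_dataset`, a single `eem`, or an
#'   `n x (n_ex * n_em)` matrix of unfolded samples on the model's axes
#'   (emission decimated the same way as at fit time).
#' @return `n x F` matrix of non-negative scores.
#' @export
project_scores <- function(model, newdata) {
  stopifnot(inherits(model, "parafac_model"))
  KR <- khatri_rao(model$em_loadings, model$ex_loadings)
  vecs <- if (inherits(newdata, "eem_dataset")) {
    if (!is.null(model$ex) &&
        !isTRUE(all.equal(as.numeric(model$ex), as.numeric(newdata$grid$ex)))) {
      stop("grid mismatch: dataset excitation axis differs from the model's", call. = FALSE)
    }
    keep <- if (is.null(model$em)) seq_len(newdata$grid$n_em) else
      match(round(model$em, 6), round(newdata$grid$em, 6))
    if (anyNA(keep)) stop("grid mismatch: model emission axis not found in dataset grid", call. = FALSE)
    t(vapply(newdata$samples,
             function(s) as.numeric(s$intensities[, keep, drop = FALSE]),
             numeric(nrow(KR))))
  } else if (inherits(newdata, "eem")) {
    project_scores(model, eem_dataset(list(newdata)))
  } else {
    as.matrix(newdata)
  }
  if (inherits(newdata, "eem")) return(vecs)
  if (ncol(vecs) != nrow(KR)) {
    stop(sprintf("unfolded sample length %d does not match model cells %d",
                 ncol(vecs), nrow(KR)), call. = FALSE)
  }
  scores <- t(apply(vecs, 1, function(v) pracma::lsqnonneg(KR, v)$x))
  if (model$n_components == 1) scores <- matrix(scores, ncol = 1)
  scores
}
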