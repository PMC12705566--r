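# --- configuration ---------------------------------------------------------

#' Configuration of the patch-attention classifier
#'
#' Hyperparameters of the transformer-encoder classifier for 1-D emission
#' spectra and 2-D EEM matrices. The defaults are deliberately small:
#' datasets of a few hundred spectra need (and can only support) a compact
#' model, and training runs on a single CPU.
#'
#' @param patch_size_2d `(ex_cells, em_cells)` patch shape for full EEM
#'   input (the matrix is zero-padded to multiples).
#' @param patch_size_1d Window length (emission points) for 1-D spectra.
#' @param embed_dim Token embedding dimension d (divisible by `n_heads`).
#' @param n_heads Attention heads h; per-head dimension is `d / h`.
#' @param depth Number of encoder blocks.
#' @param mlp_hidden Hidden width of the encoder MLPs and the
#'   classification head.
#' @param dropout_rate Dropout probability in the classification head
#'   during training, in `[0, 1)`.
#' @param n_classes Number of output classes.
#' @param learning_rate,epochs,batch_size Adam optimiser settings.
#' @param seed Integer seed making initialisation, shuffling and dropout
#'   deterministic.
#' @return An object of class `attention_config`.
#' @export
attention_config <- function(patch_size_2d = c(8, 32), patch_size_1d = 16,
                             embed_dim = 64, n_heads = 4, depth = 2,
                             mlp_hidden = 128, dropout_rate = 0.1,
                             n_classes = 3, learning_rate = 1e-3,
                             epochs = 150, batch_size = 32, seed = 1) {
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(patch_size_2d = as.integer(patch_size_2d),
                 patch_size_1d = as.integer(patch_size_1d),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 head_dim = as.integer(embed_dim / n_heads),
                 depth = as.integer(depth),
                 mlp_hidden = as.integer(mlp_hidden),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "attention_config")
}

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with row-wise softmax: every query row
#' produces a probability weighting (rows sum to 1) over the key/value
#' rows, and the output is the weighted sum of value rows.
#'
#' @param Q `n_q x d_k` query matrix.
#' @param K `n_k x d_k` key matrix.
#' @param V `n_k x d_v` value matrix.
#' @return `n_q x d_v` output with attribute `weights` (the `n_q x n_k`
#'   row-stochastic attention matrix).
#' @export
scaled_dot_product_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) {
    stop(sprintf("inner dimension mismatch: Q has %d columns, K has %d",
                 ncol(Q), ncol(K)), call. = FALSE)
  }
  if (nrow(K) != nrow(V)) {
    stop(sprintf("K has %d rows but V has %d", nrow(K), nrow(V)), call. = FALSE)
  }
  W <- row_softmax(Q %*% t(K) / sqrt(ncol(K)))
  structure(W %*% V, weights = W)
}

#' Multi-head attention over a token matrix
#'
#' Q, K, V are obtained by learned linear maps of the input; each of the
#' `h` heads runs [scaled_dot_product_attention()] on its `d/h`-dimensional
#' projection slice, the head outputs are concatenated and passed through
#' the output projection. With `h = 1` and identity projections this
#' reduces exactly to scaled dot-product self-attention.
#'
#' @param x `n_tokens x d` token matrix.
#' @param weights List with `Wq`, `Wk`, `Wv`, `Wo` (`d x d`) and optional
#'   biases `bq`, `bk`, `bv`, `bo` (length d, default 0).
#' @param h Number of heads (`d` divisible by `h`).
#' @return `n_tokens x d` matrix.
#' @export
multi_head_attention <- function(x, weights, h = 1) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (d %% h != 0) stop("embed dim must be divisible by h", call. = FALSE)
  b0 <- rep(0, d)
  Q <- x %*% weights$Wq + rep(weights$bq %||% b0, each = nrow(x))
  K <- x %*% weights$Wk + rep(weights$bk %||% b0, each = nrow(x))
  V <- x %*% weights$Wv + rep(weights$bv %||% b0, each = nrow(x))
  dk <- d %/% h
  O <- matrix(0, nrow(x), d)
  for (head in seq_len(h)) {
    cols <- ((head - 1) * dk + 1):(head * dk)
    O[, cols] <- scaled_dot_product_attention(Q[, cols, drop = FALSE],
                                              K[, cols, drop = FALSE],
                                              V[, cols, drop = FALSE])
  }
  O %*% weights$Wo + rep(weights$bo %||% b0, each = nrow(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed sinusoidal positional encoding, n_positions x d.
positional_encoding <- function(n_pos, d) {
  pos <- seq_len(n_pos) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^((i %/% 2) * 2 / d))
  P <- matrix(0, n_pos, d)
  even <- which(i %% 2 == 0)
  odd <- which(i %% 2 == 1)
  P[, even] <- sin(angle[, even, drop = FALSE])
  P[, odd] <- cos(angle[, odd, drop = FALSE])
  P
}

# Cut a 2-D matrix (zero-padded to multiples of patch) into flattened
# non-overlapping patches, row-major over (ex-block, em-block).
cut_patches_2d <- function(m, patch) {
  pr <- patch[1]; pc <- patch[2]
  nr <- ceiling(nrow(m) / pr) * pr
  nc <- ceiling(ncol(m) / pc) * pc
  padded <- matrix(0, nr, nc)
  padded[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  blocks_r <- nr / pr; blocks_c <- nc / pc
  out <- matrix(0, blocks_r * blocks_c, pr * pc)
  k <- 0
  for (br in seq_len(blocks_r)) {
    for (bc in seq_len(blocks_c)) {
      k <- k + 1
      out[k, ] <- as.numeric(padded[((br - 1) * pr + 1):(br * pr),
                                    ((bc - 1) * pc + 1):(bc * pc)])
    }
  }
  out
}

cut_patches_1d <- function(v, w) {
  n <- ceiling(length(v) / w) * w
  padded <- c(v, rep(0, n - length(v)))
  matrix(padded, ncol = w, byrow = TRUE)
}

#' Cut an EEM or emission spectrum into embedded tokens
#'
#' 2-D input is zero-padded to multiples of `patch_size_2d` and cut into
#' non-overlapping flattened patches; 1-D input is cut into
#' `patch_size_1d`-point windows; a feature vector marked with
#' `type = "features"` becomes a single token. Patches are linearly
#' embedded to dimension d, a fixed sinusoidal positional encoding is
#' added, and a learned classification token is prepended.
#'
#' @param x Matrix (2-D EEM), numeric vector (1-D spectrum or feature
#'   vector), or `eem` object.
#' @param config An [attention_config()].
#' @param weights Optional list with `W_embed`, `b_embed`, `cls`; when
#'   `NULL`, deterministic random weights derived from `config$seed` are
#'   used (standalone inspection; training supplies its own).
#' @param type `"auto"` (matrix/eem -> 2-D, vector -> 1-D windows),
#'   `"spectrum"`, or `"features"` (whole vector as one token).
#' @return List with `patches` (raw flattened patches, before embedding)
#'   and `tokens` (`(n_patches + 1) x d`, class token first).
#' @export
patchify <- function(x, config = attention_config(), weights = NULL,
                     type = c("auto", "spectrum", "features")) {
  type <- match.arg(type)
  if (inherits(x, "eem")) x <- x$intensities
  patches <- if (is.matrix(x) && type == "auto") {
    if (any(dim(x) < config$patch_size_2d)) {
      stop(sprintf("patch size %d x %d exceeds input %d x %d",
                   config$patch_size_2d[1], config$patch_size_2d[2],
                   nrow(x), ncol(x)), call. = FALSE)
    }
    cut_patches_2d(x, config$patch_size_2d)
  } else if (type == "features") {
    matrix(as.numeric(x), nrow = 1)
  } else {
    v <- as.numeric(x)
    if (config$patch_size_1d > length(v)) {
      stop(sprintf("patch size %d exceeds input length %d",
                   config$patch_size_1d, length(v)), call. = FALSE)
    }
    cut_patches_1d(v, config$patch_size_1d)
  }
  d <- config$embed_dim
  if (is.null(weights)) {
    weights <- with_seed(config$seed, {
      list(W_embed = matrix(stats::rnorm(ncol(patches) * d, 0,
                                         1 / sqrt(ncol(patches))), ncol(patches), d),
           b_embed = rep(0, d),
           cls = stats::rnorm(d, 0, 0.02))
    })
  }
  emb <- patches %*% weights$W_embed +
    rep(weights$b_embed, each = nrow(patches))
  tokens <- rbind(weights$cls, emb)
  tokens <- tokens + positional_encoding(nrow(tokens), d)
  list(patches = patches, tokens = tokens)
}

# --- forward / backward primitives ----------------------------------------

LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dgamma, db = dbeta)
}

mha_fwd <- function(x, w, h) {
  n <- nrow(x); d <- ncol(x); dk <- d %/% h
  Q <- x %*% w$Wq + rep(w$bq, each = n)
  K <- x %*% w$Wk + rep(w$bk, each = n)
  V <- x %*% w$Wv + rep(w$bv, each = n)
  A <- vector("list", h)
  O <- matrix(0, n, d)
  for (head in seq_len(h)) {
    cols <- ((head - 1) * dk + 1):(head * dk)
    Wt <- row_softmax(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    A[[head]] <- Wt
    O[, cols] <- Wt %*% V[, cols, drop = FALSE]
  }
  list(y = O %*% w$Wo + rep(w$bo, each = n),
       Q = Q, K = K, V = V, A = A, O = O, x = x)
}

mha_bwd <- function(dy, cache, w, h) {
  x <- cache$x
  n <- nrow(x); d <- ncol(x); dk <- d %/% h
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- dy %*% t(w$Wo)
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (head in seq_len(h)) {
    cols <- ((head - 1) * dk + 1):(head * dk)
    Wt <- cache$A[[head]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dWt <- dOh %*% t(Vh)
    dV[, cols] <- crossprod(Wt, dOh)
    dS <- (dWt - rowSums(dWt * Wt)) * Wt / sqrt(dk)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  list(dx = dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv),
       dWq = crossprod(x, dQ), dWk = crossprod(x, dK), dWv = crossprod(x, dV),
       dbq = colSums(dQ), dbk = colSums(dK), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

#' One transformer encoder block
#'
#' Pre-norm residual block: layer normalisation then multi-head attention
#' with a residual connection, followed by layer normalisation then a
#' two-layer ReLU MLP with a residual connection. Layer (not batch)
#' normalisation keeps per-token statistics independent of the batch
#' composition — the right choice for spectra whose intensity ranges vary
#' widely.
#'
#' @param tokens `n_tokens x d` token matrix.
#' @param weights Block weight list (`ln1_g`, `ln1_b`, `Wq` ... `bo`,
#'   `ln2_g`, `ln2_b`, `W1`, `b1`, `W2`, `b2`).
#' @param h Number of attention heads.
#' @return `n_tokens x d` matrix of the same shape.
#' @export
encoder_block <- function(tokens, weights, h = 1) {
  encoder_block_fwd(as.matrix(tokens), weights, h)$y
}

encoder_block_fwd <- function(x, w, h) {
  ln1 <- layernorm_fwd(x, w$ln1_g, w$ln1_b)
  att <- mha_fwd(ln1$y, w, h)
  x1 <- x + att$y
  ln2 <- layernorm_fwd(x1, w$ln2_g, w$ln2_b)
  pre <- ln2$y %*% w$W1 + rep(w$b1, each = nrow(x))
  hdn <- pmax(pre, 0)
  y <- x1 + hdn %*% w$W2 + rep(w$b2, each = nrow(x))
  list(y = y, ln1 = ln1, att = att, x1 = x1, ln2 = ln2, pre = pre, hdn = hdn)
}

encoder_block_bwd <- function(dy, cache, w, h) {
  dW2 <- crossprod(cache$hdn, dy)
  db2 <- colSums(dy)
  dhdn <- dy %*% t(w$W2)
  dpre <- dhdn * (cache$pre > 0)
  dW1 <- crossprod(cache$ln2$y, dpre)
  db1 <- colSums(dpre)
  dln2y <- dpre %*% t(w$W1)
  l2 <- layernorm_bwd(dln2y, cache$ln2, w$ln2_g)
  dx1 <- dy + l2$dx
  a <- mha_bwd(dx1, cache$att, w, h)
  l1 <- layernorm_bwd(a$dx, cache$ln1, w$ln1_g)
  grads <- list(ln1_g = l1$dg, ln1_b = l1$db,
                Wq = a$dWq, Wk = a$dWk, Wv = a$dWv, Wo = a$dWo,
                bq = a$dbq, bk = a$dbk, bv = a$dbv, bo = a$dbo,
                ln2_g = l2$dg, ln2_b = l2$db,
                W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  list(dx = dx1 + l1$dx, grads = grads)
}

# --- model assembly --------------------------------------------------------

init_block <- function(d, m) {
  s <- function(nin) 1 / sqrt(nin)
  list(ln1_g = rep(1, d), ln1_b = rep(0, d),
       Wq = matrix(stats::rnorm(d * d, 0, s(d)), d, d),
       Wk = matrix(stats::rnorm(d * d, 0, s(d)), d, d),
       Wv = matrix(stats::rnorm(d * d, 0, s(d)), d, d),
       Wo = matrix(stats::rnorm(d * d, 0, s(d)), d, d),
       bq = rep(0, d), bk = rep(0, d), bv = rep(0, d), bo = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d),
       W1 = matrix(stats::rnorm(d * m, 0, s(d)), d, m), b1 = rep(0, m),
       W2 = matrix(stats::rnorm(m * d, 0, s(m)), m, d), b2 = rep(0, d))
}

init_params <- function(patch_dim, cfg) {
  d <- cfg$embed_dim; m <- cfg$mlp_hidden; K <- cfg$n_classes
  p <- list(W_embed = matrix(stats::rnorm(patch_dim * d, 0, 1 / sqrt(patch_dim)),
                             patch_dim, d),
            b_embed = rep(0, d),
            cls = stats::rnorm(d, 0, 0.02))
  for (l in seq_len(cfg$depth)) p[[paste0("block", l)]] <- init_block(d, m)
  p$lnf_g <- rep(1, d); p$lnf_b <- rep(0, d)
  p$Wh <- matrix(stats::rnorm(d * m, 0, 1 / sqrt(d)), d, m); p$bh <- rep(0, m)
  p$Wc <- matrix(stats::rnorm(m * K, 0, 1 / sqrt(m)), m, K); p$bc <- rep(0, K)
  p
}

model_forward <- function(patches, params, cfg, dropout_mask = NULL) {
  n_tok <- nrow(patches) + 1L
  emb <- patches %*% params$W_embed + rep(params$b_embed, each = nrow(patches))
  tokens <- rbind(params$cls, emb) + positional_encoding(n_tok, cfg$embed_dim)
  caches <- vector("list", cfg$depth)
  x <- tokens
  for (l in seq_len(cfg$depth)) {
    caches[[l]] <- encoder_block_fwd(x, params[[paste0("block", l)]], cfg$n_heads)
    x <- caches[[l]]$y
  }
  lnf <- layernorm_fwd(x, params$lnf_g, params$lnf_b)
  clsv <- lnf$y[1, , drop = FALSE]
  pre <- clsv %*% params$Wh + matrix(params$bh, 1)
  hdn <- pmax(pre, 0)
  hdrop <- if (is.null(dropout_mask)) hdn else hdn * dropout_mask
  logits <- hdrop %*% params$Wc + matrix(params$bc, 1)
  probs <- row_softmax(logits)
  list(probs = probs, logits = logits, caches = caches, lnf = lnf, x_final = x,
       clsv = clsv, pre = pre, hdn = hdn, hdrop = hdrop, patches = patches)
}

model_backward <- function(fw, y_onehot, params, cfg, dropout_mask = NULL) {
  g <- list()
  dlogits <- fw$probs - y_onehot                 # softmax cross-entropy
  g$Wc <- crossprod(fw$hdrop, dlogits)
  g$bc <- as.numeric(dlogits)
  dhdrop <- dlogits %*% t(params$Wc)
  dhdn <- if (is.null(dropout_mask)) dhdrop else dhdrop * dropout_mask
  dpre <- dhdn * (fw$pre > 0)
  g$Wh <- crossprod(fw$clsv, dpre)
  g$bh <- as.numeric(dpre)
  dcls <- dpre %*% t(params$Wh)
  dlnf_y <- matrix(0, nrow(fw$lnf$y), ncol(fw$lnf$y))
  dlnf_y[1, ] <- dcls
  lf <- layernorm_bwd(dlnf_y, fw$lnf, params$lnf_g)
  g$lnf_g <- lf$dg; g$lnf_b <- lf$db
  dx <- lf$dx
  for (l in rev(seq_len(cfg$depth))) {
    bb <- encoder_block_bwd(dx, fw$caches[[l]], params[[paste0("block", l)]],
                            cfg$n_heads)
    g[[paste0("block", l)]] <- bb$grads
    dx <- bb$dx
  }
  g$cls <- dx[1, ]
  demb <- dx[-1, , drop = FALSE]
  g$W_embed <- crossprod(fw$patches, demb)
  g$b_embed <- colSums(demb)
  g
}

# elementwise recursion over the nested parameter list
map2_params <- function(a, b, fn) {
  out <- a
  for (nm in names(a)) {
    out[[nm]] <- if (is.list(a[[nm]])) map2_params(a[[nm]], b[[nm]], fn)
    else fn(a[[nm]], b[[nm]])
  }
  out
}

zero_like <- function(p) {
  out <- p
  for (nm in names(p)) {
    out[[nm]] <- if (is.list(p[[nm]])) zero_like(p[[nm]]) else p[[nm]] * 0
  }
  out
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mh <- 1 - beta1^t
  vh <- 1 - beta2^t
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / mh) / (sqrt(v / vh) + eps))
  params <- map2_params(params, upd, `-`)
  list(params = params, state = state)
}

# normalise labels to a factor ordered by numeric value when numeric-like
as_class_factor <- function(labels) {
  if (is.factor(labels)) return(labels)
  u <- unique(labels)
  nu <- suppressWarnings(as.numeric(as.character(u)))
  if (!anyNA(nu)) factor(labels, levels = as.character(sort(nu)))
  else factor(labels)
}

# Input scaling fitted on the training view and reapplied at inference:
# z-scores for feature vectors, a global sd divisor for spectra and EEMs
# (division only, so zero-padded cells stay zero).
fit_input_scaling <- function(x, input_type) {
  if (input_type == "features") {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    list(kind = "features", center = ctr, scale = scl)
  } else {
    s <- stats::sd(unlist(x))
    list(kind = "global", scale = if (is.finite(s) && s > 0) s else 1)
  }
}

apply_input_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  if (scaling$kind == "features") {
    sweep(sweep(as.matrix(x), 2, scaling$center), 2, scaling$scale, "/")
  } else if (is.list(x)) {
    lapply(x, function(m) m / scaling$scale)
  } else {
    x / scaling$scale
  }
}

prepare_views <- function(x, cfg, type, scaling = NULL) {
  if (inherits(x, "eem_dataset")) x <- lapply(x$samples, `[[`, "intensities")
  if (is.list(x)) {
    x <- apply_input_scaling(x, scaling)
    list(patches = lapply(x, cut_patches_2d, patch = cfg$patch_size_2d),
         input_type = "eem2d", raw = x)
  } else if (type == "features") {
    x <- apply_input_scaling(as.matrix(x), scaling)
    list(patches = lapply(seq_len(nrow(x)),
                          function(i) matrix(x[i, ], nrow = 1)),
         input_type = "features", raw = x)
  } else {
    x <- apply_input_scaling(as.matrix(x), scaling)
    list(patches = lapply(seq_len(nrow(x)),
                          function(i) cut_patches_1d(x[i, ], cfg$patch_size_1d)),
         input_type = "spectrum1d", raw = x)
  }
}

#' Train the patch-attention classifier
#'
#' Trains the transformer-encoder classifier with softmax cross-entropy
#' and the Adam optimiser. Input views: a list of 2-D EEM matrices (or an
#' `eem_dataset`), a matrix whose rows are 1-D emission spectra, or a
#' feature matrix (peak intensities or PARAFAC scores) with
#' `type = "features"`, in which case each sample enters the encoder as a
#' single token. Dropout is applied in the classification head during
#' training only; given the seed, training is fully deterministic.
#'
#' @param x Training inputs (see above).
#' @param labels Class labels, one per sample (concentration levels within
#'   one polymer in the standard design).
#' @param config An [attention_config()] (its `n_classes` is overridden by
#'   the number of observed label levels).
#' @param type `"auto"` or `"features"`.
#' @return An object of class `attention_classifier` (also
#'   `eem_classifier`) with the fitted parameters, the class levels, and a
#'   per-epoch `training_log` of mean cross-entropy loss.
#' @export
train_attention_classifier <- function(x, labels, config = attention_config(),
                                       type = c("auto", "features")) {
  type <- match.arg(type)
  y <- as_class_factor(labels)
  if (nlevels(droplevels(y)) < 2) {
    stop("training requires at least two distinct classes", call. = FALSE)
  }
  y <- droplevels(y)
  cfg <- config
  cfg$n_classes <- nlevels(y)
  views0 <- prepare_views(x, cfg, type)
  scaling <- fit_input_scaling(views0$raw, views0$input_type)
  views <- prepare_views(x, cfg, type, scaling)
  patches <- views$patches
  n <- length(patches)
  if (n != length(y)) stop("labels length does not match number of samples", call. = FALSE)
  patch_dim <- ncol(patches[[1]])
  K <- cfg$n_classes
  yi <- as.integer(y)
  with_seed(cfg$seed, {
    params <- init_params(patch_dim, cfg)
    state <- list(m = zero_like(params), v = zero_like(params))
    log <- numeric(cfg$epochs)
    t_step <- 0
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      total_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        grads <- NULL
        for (i in idx) {
          mask <- if (cfg$dropout_rate > 0) {
            matrix(stats::rbinom(cfg$mlp_hidden, 1, 1 - cfg$dropout_rate) /
                     (1 - cfg$dropout_rate), 1)
          } else NULL
          fw <- model_forward(patches[[i]], params, cfg, mask)
          onehot <- matrix(0, 1, K); onehot[1, yi[i]] <- 1
          total_loss <- total_loss - log(max(fw$probs[1, yi[i]], 1e-12))
          gi <- model_backward(fw, onehot, params, cfg, mask)
          grads <- if (is.null(grads)) gi else map2_params(grads, gi, `+`)
        }
        grads <- map2_params(grads, grads, function(g, .) g / length(idx))
        t_step <- t_step + 1
        st <- adam_step(params, grads, state, cfg$learning_rate, t_step)
        params <- st$params
        state <- st$state
      }
      log[epoch] <- total_loss / n
    }
    structure(list(kind = switch(views$input_type,
                                 eem2d = "ATTENTION_2D",
                                 spectrum1d = "ATTENTION_1D",
                                 features = "ATTENTION_FEATURES"),
                   params = params, config = cfg,
                   input_type = views$input_type, scaling = scaling,
                   classes = levels(y), training_log = log),
              class = c("attention_classifier", "eem_classifier"))
  })
}

#' @export
print.attention_classifier <- function(x, ...) {
  cat(sprintf("<attention_classifier> %s, d = %d, heads = %d, depth = %d; classes: %s; final loss %.4f\n",
              x$kind, x$config$embed_dim, x$config$n_heads, x$config$depth,
              paste(x$classes, collapse = "/"),
              x$training_log[length(x$training_log)]))
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' Dropout is disabled at inference, so repeated prediction on the same
#' input is bit-stable. Probability rows sum to 1.
#'
#' @param object A trained classifier.
#' @param newdata Same view type as at training.
#' @param type `"prob"` for the probability matrix, `"class"` for labels.
#' @param ... Unused.
#' @return `n x n_classes` probability matrix or character vector.
#' @export
predict.attention_classifier <- function(object, newdata,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  views <- prepare_views(newdata, object$config,
                         if (object$input_type == "features") "features" else "auto",
                         scaling = object$scaling)
  probs <- t(vapply(views$patches, function(p) {
    model_forward(p, object$params, object$config, NULL)$probs[1, ]
  }, numeric(object$config$n_classes)))
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, ties.method = "first")]
}
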