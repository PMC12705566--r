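# Shared fixtures (built lazily, cached across test files) and the
# independent plain CP-ALS oracle used to cross-check the package's
# nonnegative HALS implementation.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small labelled dataset with scatter + noise, all 7 groups
get_small_gen <- function() cached("small_gen", function() {
  generate_eem_dataset(n_per_group = 8, seed = 21)
})

get_small_pp <- function() cached("small_pp", function() {
  preprocess_dataset(get_small_gen()$dataset)
})

get_fixture_suite <- function() cached("worked", generate_worked_fixtures)

# full study-scale dataset (7 x 48 spectra), preprocessed and stacked with
# the emission axis decimated 8x; only the tensor is kept in memory
get_full_tensor <- function() cached("full_tensor", function() {
  gen <- generate_eem_dataset(n_per_group = 48, seed = 21)
  pp <- preprocess_dataset(gen$dataset)
  dataset_tensor(pp, decimate_em = 8)
})

get_report <- function() cached("report", function() {
  suppressMessages(pipeline_reproduce(scale = "small", seed = 42,
                                      out_dir = file.path(tempdir(), "eem_report")))
})

# --- independent oracle: plain unconstrained CP-ALS ------------------------
# Deliberately separate from the package implementation: normal-equation
# least squares per mode, no non-negativity, its own unfolding code.
plain_cp_als <- function(X, F, n_iter = 300, seed = 99) {
  d <- dim(X)
  mat_unfold <- function(X, mode) {
    perm <- c(mode, setdiff(1:3, mode))
    matrix(aperm(X, perm), dim(X)[mode])
  }
  kr <- function(U, V) {
    out <- matrix(0, nrow(U) * nrow(V), ncol(U))
    for (f in seq_len(ncol(U))) out[, f] <- kronecker(U[, f], V[, f])
    out
  }
  set.seed(seed)
  A <- matrix(runif(d[1] * F), d[1], F)
  B <- matrix(runif(d[2] * F), d[2], F)
  C <- matrix(runif(d[3] * F), d[3], F)
  X1 <- mat_unfold(X, 1); X2 <- mat_unfold(X, 2); X3 <- mat_unfold(X, 3)
  for (it in seq_len(n_iter)) {
    A <- X1 %*% kr(C, B) %*% solve(crossprod(B) * crossprod(C) + diag(1e-12, F))
    B <- X2 %*% kr(C, A) %*% solve(crossprod(A) * crossprod(C) + diag(1e-12, F))
    C <- X3 %*% kr(B, A) %*% solve(crossprod(A) * crossprod(B) + diag(1e-12, F))
  }
  Xhat <- array(A %*% t(kr(C, B)), d)
  list(A = A, B = B, C = C, fit_error = sum((X - Xhat)^2) / sum(X^2))
}

# brute-force Shapley over all p! permutation orderings (p small)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

brute_force_shapley <- function(f, instance, background) {
  p <- length(instance)
  vfun <- function(S) {
    x <- background
    x[S] <- instance[S]
    as.numeric(f(matrix(x, 1, dimnames = list(NULL, names(instance)))))
  }
  phi <- numeric(p)
  perms <- all_perms(seq_len(p))
  for (ord in perms) {
    prev <- integer(0)
    for (i in ord) {
      phi[i] <- phi[i] + vfun(c(prev, i)) - vfun(prev)
      prev <- c(prev, i)
    }
  }
  stats::setNames(phi / length(perms), names(instance))
}
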