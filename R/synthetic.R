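# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Define a Gaussian-profile fluorophore component
#'
#' Synthetic fluorophores have separable Gaussian excitation and emission
#' profiles, so a noise-free multi-sample dataset is exactly trilinear —
#' the property PARAFAC assumes — and every downstream stage can be tested
#' against known ground truth. The Stokes shift is enforced
#' (`em_center > ex_center`).
#'
#' @param name Component name.
#' @param ex_center,ex_sigma Excitation Gaussian centre and width, nm.
#' @param em_center,em_sigma Emission Gaussian centre and width, nm.
#' @param base_amplitude Peak intensity (arbitrary units) at the
#'   (ex_center, em_center) cell for a unit sample score.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, ex_center, ex_sigma, em_center, em_sigma,
                        base_amplitude = 1000) {
  if (ex_sigma <= 0 || em_sigma <= 0) stop("sigmas must be positive", call. = FALSE)
  if (em_center <= ex_center) {
    stop("em_center must exceed ex_center (Stokes shift)", call. = FALSE)
  }
  structure(list(name = name, ex_center = ex_center, ex_sigma = ex_sigma,
                 em_center = em_center, em_sigma = em_sigma,
                 base_amplitude = base_amplitude),
            class = "fluorophore")
}

#' Default five-component fluorophore catalog
#'
#' Five humic- and protein-like components at excitation/emission positions
#' typical of root-exudate dissolved organic matter: tryptophan-like
#' (305/425), tyrosine/protein-like (285/355), humic acid-like (375/475),
#' fulvic acid-like (360/430), and one broad long-wavelength composite
#' component. Widths of 15-30 nm keep the classic peak-picking windows
#' (A, M, C, D, B, T, N) attached to distinct components.
#'
#' @return List of 5 [fluorophore()] objects.
#' @export
default_fluorophore_catalog <- function() {
  list(
    fluorophore("C1_tryptophan",  ex_center = 305, ex_sigma = 20,
                em_center = 425, em_sigma = 28, base_amplitude = 1000),
    fluorophore("C2_protein",     ex_center = 285, ex_sigma = 16,
                em_center = 355, em_sigma = 22, base_amplitude = 850),
    fluorophore("C3_humic",       ex_center = 375, ex_sigma = 22,
                em_center = 475, em_sigma = 30, base_amplitude = 700),
    fluorophore("C4_fulvic",      ex_center = 360, ex_sigma = 15,
                em_center = 430, em_sigma = 20, base_amplitude = 550),
    fluorophore("C5_composite",   ex_center = 465, ex_sigma = 30,
                em_center = 560, em_sigma = 45, base_amplitude = 400)
  )
}

#' Render one fluorophore on a wavelength grid
#'
#' Outer product of the Gaussian excitation profile and the Gaussian
#' emission profile, scaled so the value at the (centre, centre) cell is
#' `base_amplitude` (up to grid snap). The result has matrix rank 1 —
#' separability is what makes stacked samples exactly trilinear.
#'
#' @param component A [fluorophore()].
#' @param grid An [eem_grid()].
#' @return `n_ex x n_em` intensity matrix.
#' @export
render_component <- function(component, grid) {
  stopifnot(inherits(component, "fluorophore"), inherits(grid, "eem_grid"))
  gx <- exp(-0.5 * ((grid$ex - component$ex_center) / component$ex_sigma)^2)
  gm <- exp(-0.5 * ((grid$em - component$em_center) / component$em_sigma)^2)
  component$base_amplitude * outer(gx, gm)
}

#' Default treatment-effect table
#'
#' Multiplicative loading factors per (component, polymer, concentration).
#' Controls are fixed at 1; low dose (10 mg/L) suppresses exudate
#' fluorescence (factors in 0.6-0.9) and high dose (100 mg/L) enhances it
#' (factors in 1.2-1.8), with polymer-specific strength ordered
#' PS > PVC > PET at high dose. Component-specific offsets make each
#' polymer's fingerprint distinct without leaving the bands.
#'
#' @param catalog Component catalog (names are taken from it).
#' @param affected_components Optional character vector restricting the
#'   effect to a subset of components (others get factor 1 at all doses) —
#'   used to build datasets with a single known discriminative component.
#' @return Data frame with columns component, polymer, concentration,
#'   factor; class `treatment_effects`.
#' @export
default_treatment_effects <- function(catalog = default_fluorophore_catalog(),
                                      affected_components = NULL) {
  comp_names <- vapply(catalog, `[[`, character(1), "name")
  polymers <- c("PET", "PS", "PVC")
  high_base <- c(PET = 1.30, PS = 1.70, PVC = 1.50)
  low_base <- c(PET = 0.85, PS = 0.70, PVC = 0.75)
  n <- length(comp_names)
  high_off <- rep_len(c(0.05, -0.05, 0.08, 0.00, -0.08), n)
  low_off <- rep_len(c(-0.03, 0.03, -0.05, 0.00, 0.05), n)
  rows <- list()
  for (p in polymers) {
    for (ci in seq_len(n)) {
      affected <- is.null(affected_components) ||
        comp_names[ci] %in% affected_components
      rows[[length(rows) + 1]] <- data.frame(
        component = comp_names[ci], polymer = p,
        concentration = c(0, 10, 100),
        factor = if (affected) {
          c(1, low_base[[p]] + low_off[ci], high_base[[p]] + high_off[ci])
        } else c(1, 1, 1))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("treatment_effects", "data.frame")
  out
}

effect_factor <- function(effects, component, polymer, concentration) {
  if (polymer == "CONTROL" || concentration == 0) return(1)
  i <- which(effects$component == component & effects$polymer == polymer &
               effects$concentration == concentration)
  if (length(i) != 1) {
    stop(sprintf("treatment-effect table is missing cell (%s, %s, %g mg/L)",
                 component, polymer, concentration), call. = FALSE)
  }
  effects$factor[i]
}

#' Measurement and scatter noise model for the generator
#'
#' @param sample_lognormal_sigma Log-scale sigma of the per-sample,
#'   per-component lognormal score scatter (biological variation between
#'   exudate samples).
#' @param additive_gaussian_sigma Standard deviation of i.i.d. additive
#'   measurement noise, intensity units.
#' @param rayleigh1_amp,rayleigh2_amp,raman_amp Peak amplitudes of the
#'   synthetic scatter ridges (0 disables a ridge).
#' @param rayleigh1_width,rayleigh2_width,raman_width Gaussian widths of
#'   the ridges along the emission axis, nm.
#' @param raman_shift Raman shift used to place the Raman ridge, cm^-1.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sample_lognormal_sigma = 0.08,
                        additive_gaussian_sigma = 10,
                        rayleigh1_amp = 2500, rayleigh2_amp = 600,
                        raman_amp = 400,
                        rayleigh1_width = 6, rayleigh2_width = 6,
                        raman_width = 4, raman_shift = 3400) {
  vals <- c(sample_lognormal_sigma, additive_gaussian_sigma,
            rayleigh1_amp, rayleigh2_amp, raman_amp,
            rayleigh1_width, rayleigh2_width, raman_width)
  if (any(vals < 0)) stop("noise model parameters must be >= 0", call. = FALSE)
  structure(list(sample_lognormal_sigma = sample_lognormal_sigma,
                 additive_gaussian_sigma = additive_gaussian_sigma,
                 rayleigh1_amp = rayleigh1_amp, rayleigh2_amp = rayleigh2_amp,
                 raman_amp = raman_amp, rayleigh1_width = rayleigh1_width,
                 rayleigh2_width = rayleigh2_width, raman_width = raman_width,
                 raman_shift = raman_shift),
            class = "noise_model")
}

render_scatter_ridges <- function(grid, noise) {
  ridge <- function(center_em, amp, width) {
    if (amp <= 0) return(0)
    em_mat <- matrix(grid$em, nrow = grid$n_ex, ncol = grid$n_em, byrow = TRUE)
    amp * exp(-0.5 * ((em_mat - center_em) / width)^2)
  }
  ridge(grid$ex, noise$rayleigh1_amp, noise$rayleigh1_width) +
    ridge(2 * grid$ex, noise$rayleigh2_amp, noise$rayleigh2_width) +
    ridge(raman_emission(grid$ex, noise$raman_shift), noise$raman_amp,
          noise$raman_width)
}

#' Generate a labelled synthetic EEM dataset with ground truth
#'
#' Emulates the study design: seven treatment groups (control plus
#' \{PET, PS, PVC\} x \{10, 100\} mg/L) with `n_per_group` samples each
#' (48 by default, 336 spectra in total). Each sample is a non-negative
#' sum of rendered fluorophores with score
#' `base loading x treatment factor x lognormal sample effect`,
#' plus Rayleigh/Raman scatter ridges and additive Gaussian noise, clipped
#' at zero. The returned ground-truth bundle carries the true scores and
#' the unit-norm excitation/emission loadings, so every downstream stage
#' (scatter removal, peak extraction, PARAFAC recovery, classification)
#' can be scored against what was actually put in.
#'
#' @param catalog List of [fluorophore()] components.
#' @param effects Treatment-effect table from [default_treatment_effects()].
#' @param noise A [noise_model()].
#' @param n_per_group Samples per treatment group.
#' @param grid An [eem_grid()].
#' @param seed Integer seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @param scatter Include scatter ridges (disable to produce scatter-free
#'   data for decomposition tests).
#' @return List with `dataset` (an `eem_dataset`) and `truth`: component
#'   matrices, unit-norm `ex_loadings` / `em_loadings`, the `scores`
#'   matrix (n_samples x F, normalisation magnitude absorbed), and the raw
#'   `raw_scores` used for rendering.
#' @export
generate_eem_dataset <- function(catalog = default_fluorophore_catalog(),
                                 effects = default_treatment_effects(catalog),
                                 noise = noise_model(),
                                 n_per_group = 48,
                                 grid = eem_grid(),
                                 seed = 1,
                                 scatter = TRUE) {
  stopifnot(n_per_group >= 1)
  comp_names <- vapply(catalog, `[[`, character(1), "name")
  groups <- data.frame(
    polymer = c("CONTROL", "PET", "PET", "PS", "PS", "PVC", "PVC"),
    concentration = c(0, 10, 100, 10, 100, 10, 100))
  comps <- lapply(catalog, render_component, grid = grid)
  ridges <- if (scatter) render_scatter_ridges(grid, noise) else 0
  n_total <- nrow(groups) * n_per_group
  F <- length(catalog)
  with_seed(seed, {
    scores <- matrix(0, n_total, F, dimnames = list(NULL, comp_names))
    samples <- vector("list", n_total)
    k <- 0
    for (gi in seq_len(nrow(groups))) {
      pol <- groups$polymer[gi]
      conc <- groups$concentration[gi]
      fac <- vapply(comp_names, function(cn)
        effect_factor(effects, cn, pol, conc), numeric(1))
      for (r in seq_len(n_per_group)) {
        k <- k + 1
        s <- fac * exp(stats::rnorm(F, 0, noise$sample_lognormal_sigma))
        scores[k, ] <- s
        m <- Reduce(`+`, Map(function(sc, cm) sc * cm, s, comps)) + ridges
        if (noise$additive_gaussian_sigma > 0) {
          m <- m + matrix(stats::rnorm(length(m), 0, noise$additive_gaussian_sigma),
                          nrow = nrow(m))
        }
        m[m < 0] <- 0
        samples[[k]] <- eem_sample(
          sprintf("%s_%03g_s%03d", pol, conc, r), m, grid,
          polymer = pol, concentration = conc, replicate_index = 0L)
      }
    }
    ex_loadings <- vapply(catalog, function(cp)
      exp(-0.5 * ((grid$ex - cp$ex_center) / cp$ex_sigma)^2), numeric(grid$n_ex))
    em_loadings <- vapply(catalog, function(cp)
      exp(-0.5 * ((grid$em - cp$em_center) / cp$em_sigma)^2), numeric(grid$n_em))
    amp <- vapply(catalog, `[[`, numeric(1), "base_amplitude")
    ex_norm <- sqrt(colSums(ex_loadings^2))
    em_norm <- sqrt(colSums(em_loadings^2))
    truth <- list(
      components = comps,
      ex_loadings = sweep(ex_loadings, 2, ex_norm, "/"),
      em_loadings = sweep(em_loadings, 2, em_norm, "/"),
      scores = sweep(scores, 2, amp * ex_norm * em_norm, "*"),
      raw_scores = scores,
      catalog = catalog, groups = groups, noise = noise)
    list(dataset = eem_dataset(samples), truth = truth)
  })
}

#' Scatter-free noise-free reconstruction of one generated sample
#'
#' @param truth Ground-truth bundle from [generate_eem_dataset()].
#' @param i Sample index in dataset order.
#' @return The clean `n_ex x n_em` matrix underlying sample `i`.
#' @export
truth_clean_matrix <- function(truth, i) {
  Reduce(`+`, Map(function(sc, cm) sc * cm, truth$raw_scores[i, ], truth$components))
}

#' Deterministic miniature fixtures for decomposition tests
#'
#' Emits the small tensors shared across the test-suite: an exact rank-1
#' tensor (outer product of three positive vectors), an exact 3-component
#' trilinear tensor with its generating loadings, and a 2 x 3 toy EEM.
#' Checksums (rounded sums of entries) make accidental regeneration drift
#' detectable.
#'
#' @return List with `rank1` (tensor + vectors), `rank3` (tensor + loading
#'   matrices A, B, C), `toy_eem` (an `eem` on a tiny grid), and
#'   `checksums`.
#' @export
generate_worked_fixtures <- function() {
  u <- 1 + sin(seq_len(20))^2
  v <- 1 + cos(seq_len(10))^2
  w <- exp(-seq_len(15) / 10)
  rank1 <- outer(outer(u, v), w)
  with_seed(424242, {
    A <- matrix(stats::runif(20 * 3, 0.2, 1), 20, 3)
    B <- matrix(stats::runif(10 * 3, 0.2, 1), 10, 3)
    C <- matrix(stats::runif(15 * 3, 0.2, 1), 15, 3)
  })
  rank3 <- cp_compose(A, B, C)
  toy_grid <- eem_grid(220, 225, 5, 240, 242, 1)
  toy <- eem_sample("toy", matrix(0:5, 2, 3, byrow = TRUE), toy_grid)
  list(rank1 = list(tensor = rank1, u = u, v = v, w = w),
       rank3 = list(tensor = rank3, A = A, B = B, C = C),
       toy_eem = toy,
       checksums = list(rank1 = round(sum(rank1), 6),
                        rank3 = round(sum(rank3), 6),
                        toy = sum(toy$intensities)))
}
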