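#' Scatter-removal configuration
#'
#' Geometry and smoothing parameters for Rayleigh/Raman scatter removal.
#' Band half-widths are in nm along the emission axis; the Raman ridge is
#' located from the water O-H stretch wavenumber shift (default 3400 cm^-1),
#' which puts the first-order Raman line of a 350 nm excitation near 397 nm.
#'
#' @param rayleigh1_halfwidth Half-width of the first-order Rayleigh band
#'   (em = ex), nm.
#' @param rayleigh2_halfwidth Half-width of the second-order Rayleigh band
#'   (em = 2 ex), nm.
#' @param raman_shift Raman wavenumber shift, cm^-1.
#' @param raman_halfwidth Half-width of the Raman band, nm.
#' @param smoothing_window Odd window length (emission points) of the
#'   centred moving average.
#' @param nonphysical_margin Extra margin (nm) added to the excitation
#'   wavelength when zeroing the non-physical em < ex region.
#' @return An object of class `scatter_config`.
#' @export
scatter_config <- function(rayleigh1_halfwidth = 15, rayleigh2_halfwidth = 15,
                           raman_shift = 3400, raman_halfwidth = 10,
                           smoothing_window = 11, nonphysical_margin = 0) {
  if (rayleigh1_halfwidth <= 0 || rayleigh2_halfwidth <= 0 || raman_halfwidth <= 0) {
    stop("scatter band half-widths must be positive", call. = FALSE)
  }
  if (raman_shift <= 0) stop("raman_shift must be positive", call. = FALSE)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 3 || smoothing_window %% 2 == 0) {
    stop("smoothing_window must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(rayleigh1_halfwidth = rayleigh1_halfwidth,
                 rayleigh2_halfwidth = rayleigh2_halfwidth,
                 raman_shift = raman_shift, raman_halfwidth = raman_halfwidth,
                 smoothing_window = smoothing_window,
                 nonphysical_margin = nonphysical_margin),
            class = "scatter_config")
}

#' Emission wavelength of the Raman scatter line
#'
#' For excitation at `ex` nm and a Raman shift of `shift` cm^-1 the
#' scattered line sits at `1 / (1/ex - shift * 1e-7)` nm (wavenumber
#' subtraction; 1 cm^-1 = 1e-7 nm^-1).
#'
#' @param ex Excitation wavelength(s), nm.
#' @param shift Raman shift, cm^-1.
#' @return Emission wavelength(s), nm.
#' @export
raman_emission <- function(ex, shift = 3400) {
  1 / (1 / ex - shift * 1e-7)
}

#' Boolean mask of scatter-affected EEM cells
#'
#' A cell (ex, em) is flagged as scatter when it lies within the configured
#' half-width of any of three ridges: first-order Rayleigh (em = ex),
#' second-order Rayleigh (em = 2 ex), or first-order Raman
#' (em = [raman_emission()] of ex).
#'
#' @param grid An [eem_grid()].
#' @param config A [scatter_config()].
#' @return Logical `n_ex x n_em` matrix, `TRUE` = scatter.
#' @export
scatter_mask <- function(grid, config = scatter_config()) {
  stopifnot(inherits(grid, "eem_grid"), inherits(config, "scatter_config"))
  ex <- grid$ex
  em <- grid$em
  em_mat <- matrix(em, nrow = grid$n_ex, ncol = grid$n_em, byrow = TRUE)
  r1 <- abs(em_mat - ex) <= config$rayleigh1_halfwidth
  r2 <- abs(em_mat - 2 * ex) <= config$rayleigh2_halfwidth
  ram <- abs(em_mat - raman_emission(ex, config$raman_shift)) <= config$raman_halfwidth
  m <- r1 | r2 | ram
  dimnames(m) <- list(ex, em)
  m
}

# Linear interpolation of masked runs along one emission row; edge runs are
# filled by nearest-value extension (approx rule = 2).
interp_row <- function(row, masked) {
  if (!any(masked)) return(row)
  if (all(masked)) return(NULL)
  x <- seq_along(row)
  filled <- stats::approx(x[!masked], row[!masked], xout = x[masked],
                          method = "linear", rule = 2)$y
  row[masked] <- filled
  row
}

#' Replace masked scatter cells by emission-axis interpolation
#'
#' Masked cells are replaced by linear interpolation along the emission axis
#' between the nearest unmasked neighbours of the same excitation row; runs
#' touching a row edge are filled by extending the nearest unmasked value.
#' Unmasked cells are unchanged. Interpolation runs along emission rows
#' only, matching the per-emission-row treatment of the 1-D pipeline.
#'
#' @param sample An `eem` object (masked cells may be `NA` already).
#' @param mask Logical matrix from [scatter_mask()]; defaults to treating
#'   existing `NA` cells as the mask.
#' @return The sample with all masked cells filled.
#' @export
interpolate_masked <- function(sample, mask = is.na(sample$intensities)) {
  stopifnot(inherits(sample, "eem"))
  m <- sample$intensities
  if (!all(dim(mask) == dim(m))) stop("mask shape does not match sample", call. = FALSE)
  mask <- mask | is.na(m)
  for (i in seq_len(nrow(m))) {
    out <- interp_row(m[i, ], mask[i, ])
    if (is.null(out)) {
      stop(sprintf("emission row at excitation %g nm is fully masked; cannot interpolate",
                   sample$grid$ex[i]), call. = FALSE)
    }
    m[i, ] <- out
  }
  sample$intensities <- m
  sample
}

# Centred moving average with shrinking windows at the edges, vectorised
# over rows via cumulative sums. w must be odd.
moving_average_rows <- function(m, w) {
  h <- (w - 1L) %/% 2L
  n <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  j <- seq_len(n)
  lo <- pmax(j - h, 1L)
  hi <- pmin(j + h, n)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1L, nrow = nrow(m), ncol = n, byrow = TRUE)
}

#' Moving-average smoothing along the emission axis
#'
#' Each emission row is replaced by its centred moving average; near the row
#' edges the window shrinks symmetrically so output length equals input
#' length. Averaging cannot leave the row's original range.
#'
#' @param sample An `eem` with no missing values.
#' @param window Odd window length in emission points, `<= n_em`.
#' @return Smoothed sample.
#' @export
smooth_emission <- function(sample, window = 11) {
  stopifnot(inherits(sample, "eem"))
  window <- as.integer(window)
  if (window %% 2 == 0 || window < 1) {
    stop("smoothing window must be a positive odd integer", call. = FALSE)
  }
  if (window > sample$grid$n_em) stop("smoothing window exceeds emission axis length", call. = FALSE)
  if (anyNA(sample$intensities)) stop("smooth_emission requires interpolated (NA-free) input", call. = FALSE)
  sample$intensities <- moving_average_rows(sample$intensities, window)
  dimnames(sample$intensities) <- list(sample$grid$ex, sample$grid$em)
  sample
}

#' Zero the non-physical region below the excitation line
#'
#' Emitted photons carry less energy than the exciting photon (Stokes
#' shift), so intensity recorded at em < ex + margin is non-physical and is
#' set to zero.
#'
#' @param sample An `eem`.
#' @param margin Extra nm added to the excitation wavelength.
#' @return Sample with the triangular region zeroed.
#' @export
zero_nonphysical <- function(sample, margin = 0) {
  stopifnot(inherits(sample, "eem"))
  g <- sample$grid
  em_mat <- matrix(g$em, nrow = g$n_ex, ncol = g$n_em, byrow = TRUE)
  sample$intensities[em_mat < g$ex + margin] <- 0
  sample
}

#' Full EEM scatter-removal pipeline
#'
#' Composition of the four preprocessing stages, in this order: mask the
#' Rayleigh/Raman ridges, interpolate the masked cells along emission rows,
#' moving-average smooth each emission row, then zero the non-physical
#' em < ex region (zeroing last, so interpolation cannot leak into the
#' triangle). Any negative intensities left by smoothing are clipped to 0.
#'
#' @param sample A raw `eem`.
#' @param config A [scatter_config()].
#' @return Preprocessed sample: no missing values, no negatives, zeros
#'   wherever em < ex + margin.
#' @export
preprocess_eem <- function(sample, config = scatter_config()) {
  stopifnot(inherits(sample, "eem"), inherits(config, "scatter_config"))
  mask <- scatter_mask(sample$grid, config)
  out <- interpolate_masked(sample, mask)
  out <- smooth_emission(out, config$smoothing_window)
  out <- zero_nonphysical(out, config$nonphysical_margin)
  out$intensities[out$intensities < 0] <- 0
  out
}

#' @rdname preprocess_eem
#' @param dataset An `eem_dataset`.
#' @return `preprocess_dataset` returns the dataset with every sample
#'   preprocessed.
#' @export
preprocess_dataset <- function(dataset, config = scatter_config()) {
  stopifnot(inherits(dataset, "eem_dataset"))
  dataset$samples <- lapply(dataset$samples, preprocess_eem, config = config)
  dataset
}
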