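#' Define a characteristic fluorescence peak window
#'
#' @param label Peak label (one of the classic A, M, C, D, B, T, N).
#' @param ex_lo,ex_hi Excitation window, nm (`lo == hi` for a point peak).
#' @param em_lo,em_hi Emission window, nm.
#' @param substance Substance assignment, free text.
#' @return An object of class `peak_definition`.
#' @export
peak_definition <- function(label, ex_lo, ex_hi = ex_lo, em_lo, em_hi = em_lo,
                            substance = "") {
  if (ex_lo > ex_hi || em_lo > em_hi) {
    stop("peak window bounds must satisfy lo <= hi", call. = FALSE)
  }
  structure(list(label = label, ex_lo = ex_lo, ex_hi = ex_hi,
                 em_lo = em_lo, em_hi = em_hi, substance = substance),
            class = "peak_definition")
}

#' Catalog of the seven classic characteristic fluorescence peaks
#'
#' The conventional peak families used to fingerprint dissolved organic
#' matter in root exudates: UV humic acid (A), marine humic acid (M),
#' visible humic acid (C), fulvic acid (D), tyrosine-like (B),
#' tryptophan-like (T) and phytoplankton-related (N) compounds. Point
#' positions are represented as degenerate windows (`lo == hi`).
#'
#' @return Named list of 7 [peak_definition()] objects, in catalog order
#'   A, M, C, D, B, T, N.
#' @export
default_peak_catalog <- function() {
  defs <- list(
    peak_definition("A", 260, 260, 400, 460, "UV humic acid"),
    peak_definition("M", 290, 310, 370, 410, "Marine humic acid"),
    peak_definition("C", 320, 360, 420, 460, "Visible humic acid"),
    peak_definition("D", 390, 390, 509, 509, "Fulvic acid"),
    peak_definition("B", 275, 275, 305, 305, "Tyrosine-like compound"),
    peak_definition("T", 275, 275, 340, 340, "Tryptophan-like compound"),
    peak_definition("N", 280, 280, 370, 370, "Phytoplankton-related compound")
  )
  names(defs) <- vapply(defs, `[[`, character(1), "label")
  defs
}

# Snap a wavelength window to grid indices (nearest grid lines; point
# windows snap to a single cell).
window_indices <- function(axis, lo, hi, axis_name) {
  if (hi < min(axis) || lo > max(axis)) {
    stop(sprintf("peak window %g-%g nm lies outside the %s axis (%g-%g nm)",
                 lo, hi, axis_name, min(axis), max(axis)), call. = FALSE)
  }
  i_lo <- which.min(abs(axis - lo))
  i_hi <- which.min(abs(axis - hi))
  seq(min(i_lo, i_hi), max(i_lo, i_hi))
}

#' Extract one characteristic peak intensity from an EEM
#'
#' Returns the window statistic of the intensities over all grid cells
#' inside the peak's excitation/emission window (snapped to the nearest
#' grid lines). The default statistic is the window mean — robust to
#' single-pixel noise; `"max"` is available as an alternative. Degenerate
#' windows return the single cell value under either statistic.
#'
#' @param sample A preprocessed `eem`.
#' @param peak A [peak_definition()].
#' @param statistic `"mean"` (default) or `"max"`.
#' @return Scalar intensity.
#' @export
extract_peak <- function(sample, peak, statistic = c("mean", "max")) {
  stopifnot(inherits(sample, "eem"), inherits(peak, "peak_definition"))
  statistic <- match.arg(statistic)
  g <- sample$grid
  ii <- window_indices(g$ex, peak$ex_lo, peak$ex_hi, "excitation")
  jj <- window_indices(g$em, peak$em_lo, peak$em_hi, "emission")
  vals <- sample$intensities[ii, jj]
  if (statistic == "mean") mean(vals) else max(vals)
}

#' Build the per-sample peak intensity table for a dataset
#'
#' @param dataset An `eem_dataset` of preprocessed samples.
#' @param catalog Peak catalog (default [default_peak_catalog()]).
#' @param statistic Window statistic, see [extract_peak()].
#' @return Data frame of class `peak_table`: `sample_id`, one column per
#'   peak label in catalog order, then `polymer` and `concentration`; rows
#'   follow dataset order.
#' @export
build_peak_table <- function(dataset, catalog = default_peak_catalog(),
                             statistic = "mean") {
  stopifnot(inherits(dataset, "eem_dataset"))
  labels <- vapply(catalog, `[[`, character(1), "label")
  if (length(dataset$samples) == 0) {
    out <- data.frame(sample_id = character())
    for (l in labels) out[[l]] <- numeric()
    out$polymer <- character(); out$concentration <- numeric()
    class(out) <- c("peak_table", "data.frame")
    return(out)
  }
  vals <- t(vapply(dataset$samples, function(s) {
    vapply(catalog, function(p) extract_peak(s, p, statistic), numeric(1))
  }, numeric(length(catalog))))
  out <- data.frame(sample_id = dataset$manifest$sample_id, vals,
                    polymer = dataset$manifest$polymer,
                    concentration = dataset$manifest$concentration,
                    row.names = NULL, check.names = FALSE)
  colnames(out)[seq_along(labels) + 1] <- labels
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Numeric feature matrix of a peak (or score) table
#'
#' @param table A `peak_table` or any data frame with `sample_id`,
#'   feature columns, `polymer`, `concentration`.
#' @return Numeric matrix (rownames = sample ids) of the feature columns.
#' @export
feature_matrix <- function(table) {
  feat_cols <- setdiff(colnames(table), c("sample_id", "polymer", "concentration"))
  m <- as.matrix(table[, feat_cols, drop = FALSE])
  rownames(m) <- table$sample_id
  storage.mode(m) <- "double"
  m
}
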