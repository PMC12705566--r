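#' Define an excitation/emission wavelength grid
#'
#' An EEM (excitation-emission matrix) is recorded on a regular wavelength
#' grid: one excitation axis (matrix rows) and one emission axis (matrix
#' columns), both inclusive of their endpoints. The default instrument grid
#' used throughout the package scans excitation 220-550 nm in 5 nm steps and
#' emission 240-750 nm in 1 nm steps, giving a 67 x 511 intensity matrix
#' (34,237 cells per spectrum).
#'
#' @param ex_start,ex_stop,ex_step Excitation axis in nm; the range must
#'   divide evenly by the step.
#' @param em_start,em_stop,em_step Emission axis in nm, same constraint.
#' @return An object of class `eem_grid` with the axis parameters, the
#'   explicit axes (`ex`, `em`) and their lengths (`n_ex`, `n_em`).
#' @examples
#' g <- eem_grid()
#' g$n_ex * g$n_em  # 34237
#' @export
eem_grid <- function(ex_start = 220, ex_stop = 550, ex_step = 5,
                     em_start = 240, em_stop = 750, em_step = 1) {
  check_axis <- function(start, stop, step, axis) {
    if (!is.finite(start) || !is.finite(stop) || !is.finite(step)) {
      stop(sprintf("invalid grid: non-finite %s axis parameters", axis), call. = FALSE)
    }
    if (stop <= start) {
      stop(sprintf("invalid grid: %s_stop must exceed %s_start", axis, axis), call. = FALSE)
    }
    if (step <= 0) {
      stop(sprintf("invalid grid: %s_step must be positive", axis), call. = FALSE)
    }
    span <- stop - start
    if (abs(span / step - round(span / step)) > 1e-9) {
      stop(sprintf("invalid grid: %s range %g-%g does not divide evenly by step %g",
                   axis, start, stop, step), call. = FALSE)
    }
    invisible(NULL)
  }
  check_axis(ex_start, ex_stop, ex_step, "ex")
  check_axis(em_start, em_stop, em_step, "em")
  ex <- seq(ex_start, ex_stop, by = ex_step)
  em <- seq(em_start, em_stop, by = em_step)
  structure(
    list(ex_start = ex_start, ex_stop = ex_stop, ex_step = ex_step,
         em_start = em_start, em_stop = em_stop, em_step = em_step,
         ex = ex, em = em, n_ex = length(ex), n_em = length(em)),
    class = "eem_grid"
  )
}

#' @export
print.eem_grid <- function(x, ...) {
  cat(sprintf("<eem_grid> ex %g-%g nm step %g (%d), em %g-%g nm step %g (%d); %d cells\n",
              x$ex_start, x$ex_stop, x$ex_step, x$n_ex,
              x$em_start, x$em_stop, x$em_step, x$n_em, x$n_ex * x$n_em))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unlist(a[c("ex_start", "ex_stop", "ex_step",
                              "em_start", "em_stop", "em_step")]),
                   unlist(b[c("ex_start", "ex_stop", "ex_step",
                              "em_start", "em_stop", "em_step")])))
}

POLYMERS <- c("CONTROL", "PET", "PS", "PVC")
CONCENTRATIONS <- c(0, 10, 100)

#' Construct a single labelled EEM sample
#'
#' Wraps one intensity matrix (rows = excitation, columns = emission) with
#' its wavelength grid and treatment labels. The label pair is constrained:
#' polymer `"CONTROL"` if and only if concentration is 0 mg/L.
#'
#' @param sample_id Unique sample identifier string.
#' @param intensities Numeric `n_ex x n_em` matrix; `NA` cells are allowed
#'   mid-pipeline (masked scatter), negative values only before
#'   preprocessing.
#' @param grid An [eem_grid()].
#' @param polymer One of `"CONTROL"`, `"PET"`, `"PS"`, `"PVC"`.
#' @param concentration Dose in mg/L, one of 0, 10, 100.
#' @param replicate_index Non-negative integer, kept for generators that
#'   emit raw instrument repeats (repeats are averaged upstream).
#' @return An object of class `eem`.
#' @export
eem_sample <- function(sample_id, intensities, grid,
                       polymer = "CONTROL", concentration = 0,
                       replicate_index = 0L) {
  stopifnot(inherits(grid, "eem_grid"))
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities)) stop("intensities must be numeric", call. = FALSE)
  if (nrow(intensities) != grid$n_ex || ncol(intensities) != grid$n_em) {
    stop(sprintf("intensity matrix is %d x %d but grid requires %d x %d",
                 nrow(intensities), ncol(intensities), grid$n_ex, grid$n_em),
         call. = FALSE)
  }
  polymer <- match.arg(polymer, POLYMERS)
  if (!concentration %in% CONCENTRATIONS) {
    stop("concentration must be one of 0, 10, 100 mg/L", call. = FALSE)
  }
  if ((polymer == "CONTROL") != (concentration == 0)) {
    stop("polymer CONTROL if and only if concentration is 0 mg/L", call. = FALSE)
  }
  dimnames(intensities) <- list(grid$ex, grid$em)
  structure(
    list(sample_id = as.character(sample_id), intensities = intensities,
         grid = grid, polymer = polymer, concentration = concentration,
         replicate_index = as.integer(replicate_index)),
    class = "eem"
  )
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %s [%s, %g mg/L] %d x %d, range %.3g-%.3g%s\n",
              x$sample_id, x$polymer, x$concentration,
              x$grid$n_ex, x$grid$n_em,
              min(x$intensities, na.rm = TRUE), max(x$intensities, na.rm = TRUE),
              if (anyNA(x$intensities)) sprintf(", %d NA", sum(is.na(x$intensities))) else ""))
  invisible(x)
}

#' Assemble EEM samples into a labelled dataset
#'
#' All samples must share one grid and carry unique identifiers. The
#' manifest (one row per sample: id, polymer, concentration) doubles as the
#' label table for classification.
#'
#' @param samples List of [eem_sample()] objects.
#' @return An object of class `eem_dataset` with elements `samples`, `grid`
#'   and `manifest` (a data.frame).
#' @export
eem_dataset <- function(samples) {
  if (length(samples) == 0) {
    return(structure(list(samples = list(), grid = NULL,
                          manifest = data.frame(sample_id = character(),
                                                polymer = character(),
                                                concentration = numeric())),
                     class = "eem_dataset"))
  }
  stopifnot(all(vapply(samples, inherits, logical(1), "eem")))
  grid <- samples[[1]]$grid
  for (s in samples) {
    if (!grids_equal(s$grid, grid)) {
      stop("all samples in a dataset must share one wavelength grid", call. = FALSE)
    }
  }
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample_id: %s", ids[duplicated(ids)][1]), call. = FALSE)
  }
  names(samples) <- ids
  manifest <- data.frame(
    sample_id = ids,
    polymer = vapply(samples, `[[`, character(1), "polymer"),
    concentration = vapply(samples, `[[`, numeric(1), "concentration"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(samples = samples, grid = grid, manifest = manifest),
            class = "eem_dataset")
}

#' @export
print.eem_dataset <- function(x, ...) {
  cat(sprintf("<eem_dataset> %d samples", length(x$samples)))
  if (length(x$samples)) {
    tab <- table(paste(x$manifest$polymer, x$manifest$concentration))
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.eem_dataset <- function(x) length(x$samples)

#' Write / read one EEM sample as CSV
#'
#' The CSV layout is self-describing: a header row of emission wavelengths,
#' a leading `ex_nm` column of excitation wavelengths, and one intensity per
#' cell. Masked intensities are serialised as the literal token `NA` so that
#' masked files remain diff-able. A write -> read round trip reproduces the
#' matrix to full printed precision.
#'
#' @param sample An `eem` object.
#' @param path File path.
#' @param digits Significant digits written (default 15, i.e. effectively
#'   lossless for double precision).
#' @return `write_eem_csv` returns `path` invisibly.
#' @export
write_eem_csv <- function(sample, path, digits = 15) {
  stopifnot(inherits(sample, "eem"))
  m <- sample$intensities
  df <- data.frame(ex_nm = sample$grid$ex,
                   signif(m, digits),
                   check.names = FALSE)
  colnames(df) <- c("ex_nm", format(sample$grid$em, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_eem_csv
#' @param grid Expected [eem_grid()]; the file's wavelength axes must match
#'   it exactly or a grid-mismatch error names the first differing
#'   wavelength.
#' @param sample_id,polymer,concentration Label metadata for the returned
#'   sample (the CSV stores intensities only; labels live in the manifest).
#' @return `read_eem_csv` returns an `eem` object.
#' @export
read_eem_csv <- function(path, grid, sample_id = basename(path),
                         polymer = "CONTROL", concentration = 0) {
  stopifnot(inherits(grid, "eem_grid"))
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "NA",
                        colClasses = "character")
  em_file <- suppressWarnings(as.numeric(colnames(df)[-1]))
  ex_file <- suppressWarnings(as.numeric(df[[1]]))
  if (anyNA(em_file)) {
    stop(sprintf("parse error in %s: non-numeric emission header at column %d",
                 path, which(is.na(em_file))[1] + 1L), call. = FALSE)
  }
  if (anyNA(ex_file)) {
    stop(sprintf("parse error in %s: non-numeric excitation value at row %d",
                 path, which(is.na(ex_file))[1]), call. = FALSE)
  }
  check_match <- function(file_axis, grid_axis, axis) {
    if (length(file_axis) != length(grid_axis) ||
        any(abs(file_axis - grid_axis) > 1e-6)) {
      n <- min(length(file_axis), length(grid_axis))
      d <- which(abs(file_axis[seq_len(n)] - grid_axis[seq_len(n)]) > 1e-6)
      first <- if (length(d)) file_axis[d[1]] else
        c(file_axis, grid_axis)[n + 1]
      stop(sprintf("grid mismatch in %s: %s axis differs from grid starting at %g nm",
                   path, axis, first), call. = FALSE)
    }
  }
  check_match(em_file, grid$em, "emission")
  check_match(ex_file, grid$ex, "excitation")
  cells <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(cells), nrow = grid$n_ex))
  bad <- is.na(m) & !(is.na(cells) | cells == "NA")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("parse error in %s: malformed cell at row %d (ex %g nm), column %d (em %g nm)",
                 path, idx[1], grid$ex[idx[1]], idx[2], grid$em[idx[2]]), call. = FALSE)
  }
  eem_sample(sample_id, m, grid, polymer = polymer, concentration = concentration)
}

#' Write / read a dataset manifest as JSON
#'
#' The manifest is a JSON array of records `{sample_id, file, polymer,
#' concentration_mg_per_L}` alongside per-sample EEM CSV files.
#'
#' @param dataset An `eem_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_eem_dataset` returns the manifest path invisibly;
#'   `read_eem_dataset` returns an `eem_dataset`.
#' @export
write_eem_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eem_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(dataset$manifest$sample_id, ".csv")
  for (i in seq_along(dataset$samples)) {
    write_eem_csv(dataset$samples[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(sample_id = dataset$manifest$sample_id,
                         file = files,
                         polymer = dataset$manifest$polymer,
                         concentration_mg_per_L = dataset$manifest$concentration)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_eem_dataset
#' @param grid Expected grid for every sample file.
#' @export
read_eem_dataset <- function(dir, grid) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    read_eem_csv(file.path(dir, manifest$file[i]), grid,
                 sample_id = manifest$sample_id[i],
                 polymer = manifest$polymer[i],
                 concentration = manifest$concentration_mg_per_L[i])
  })
  eem_dataset(samples)
}

#' Extract the emission spectrum at one excitation wavelength
#'
#' Returns the single matrix row recorded at excitation `ex_nm` — the 1-D
#' emission spectrum used by the per-excitation classifiers and by scatter
#' diagnostics.
#'
#' @param sample An `eem` object.
#' @param ex_nm Excitation wavelength; must lie on the grid's excitation
#'   axis, otherwise the error suggests the two nearest grid wavelengths.
#' @return Named numeric vector of length `n_em`.
#' @export
extract_emission_slice <- function(sample, ex_nm) {
  stopifnot(inherits(sample, "eem"))
  g <- sample$grid
  i <- which(abs(g$ex - ex_nm) < 1e-9)
  if (length(i) != 1) {
    below <- max(g$ex[g$ex < ex_nm], -Inf)
    above <- min(g$ex[g$ex > ex_nm], Inf)
    stop(sprintf("excitation %g nm is not on the grid; nearest axis wavelengths are %g and %g nm",
                 ex_nm, below, above), call. = FALSE)
  }
  sample$intensities[i, ]
}
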