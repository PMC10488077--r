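#' Construct an FTIR spectrum
#'
#' A spectrum is a pair of equal-length numeric vectors: a strictly monotonic
#' wavenumber grid (cm^-1, typically stored descending as acquired) and the
#' absorbance at each grid point (arbitrary units).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic (ascending or descending).
#' @param absorbance Numeric vector of absorbance values, same length.
#' @return An object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumbers and absorbance must have the same length")
  }
  if (length(wavenumbers) < 2) stop("a spectrum needs at least two points")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance))) {
    stop("spectrum values must all be finite")
  }
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotonic")
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %d points, %g to %g cm^-1\n",
              length(x$wavenumbers), x$wavenumbers[1],
              x$wavenumbers[length(x$wavenumbers)]))
  invisible(x)
}

#' Construct a depth-ordered FTIR spectral series
#'
#' A series holds an ordered stack of spectra sharing one wavenumber grid.
#' The layer order is the perturbation axis for depth-resolved two-dimensional
#' correlation analysis: layer 1 is the most anterior stromal layer and the
#' last layer the most posterior.
#'
#' @param wavenumbers Shared wavenumber grid (cm^-1), strictly monotonic.
#' @param absorbance Numeric matrix, `length(wavenumbers)` rows, one column
#'   per layer in anterior-to-posterior order.
#' @param layer_names Optional column labels; defaults to `layer_01` style.
#' @return An object of class `ftir_series`.
#' @export
ftir_series <- function(wavenumbers, absorbance, layer_names = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(wavenumbers)) {
    stop("absorbance must have one row per wavenumber")
  }
  if (ncol(absorbance) < 1) stop("series needs at least one layer")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance))) {
    stop("series values must all be finite")
  }
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotonic")
  }
  if (is.null(layer_names)) {
    layer_names <- sprintf("layer_%02d", seq_len(ncol(absorbance)))
  }
  colnames(absorbance) <- layer_names
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance),
            class = "ftir_series")
}

#' @export
print.ftir_series <- function(x, ...) {
  cat(sprintf("<ftir_series> %d layers x %d wavenumbers (%g to %g cm^-1)\n",
              ncol(x$absorbance), length(x$wavenumbers), x$wavenumbers[1],
              x$wavenumbers[length(x$wavenumbers)]))
  invisible(x)
}

#' Number of layers in a series
#' @param series An `ftir_series`.
#' @return Integer layer count.
#' @export
n_layers <- function(series) {
  stopifnot(inherits(series, "ftir_series"))
  ncol(series$absorbance)
}

#' Read a depth series from a CSV matrix
#'
#' The expected dialect is the one written by [write_spectral_series()]:
#' first column `wavenumber` (cm^-1), remaining columns `layer_01` ...
#' `layer_NN` in anterior-to-posterior order. Rows in shuffled wavenumber
#' order are sorted descending with a warning; ragged rows, non-numeric
#' cells and duplicate wavenumbers are errors naming the offending row.
#'
#' @param path Path to the CSV file.
#' @return An `ftir_series`.
#' @export
read_spectral_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectral CSV needs a wavenumber column plus layers")
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell in column '%s', data row %d",
                   names(df)[j], bad))
    }
    df[[j]] <- v
  }
  wn <- df[[1]]
  if (anyDuplicated(wn)) {
    bad <- which(duplicated(wn))[1]
    stop(sprintf("duplicate wavenumber %g at data row %d", wn[bad], bad))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  d <- diff(wn)
  if (!(all(d > 0) || all(d < 0))) {
    warning("wavenumber rows out of order; sorting descending")
    o <- order(wn, decreasing = TRUE)
    wn <- wn[o]
    mat <- mat[o, , drop = FALSE]
  }
  ftir_series(wn, mat, layer_names = colnames(mat))
}

#' Write a depth series as a CSV matrix
#'
#' @param series An `ftir_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_series <- function(series, path) {
  stopifnot(inherits(series, "ftir_series"))
  df <- data.frame(wavenumber = series$wavenumbers, check.names = FALSE)
  df <- cbind(df, as.data.frame(series$absorbance, check.names = FALSE))
  # 17 significant digits so the CSV round-trips doubles exactly
  out <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
  utils::write.table(rbind(colnames(df), out), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coadd (average) layers of a series
#'
#' Pointwise mean of the selected layer spectra, the standard way a single
#' representative spectrum is formed from a scanned region of interest.
#'
#' @param series An `ftir_series`.
#' @param layers Integer indices of layers to average; default all.
#' @return An `ftir_spectrum`.
#' @export
coadd <- function(series, layers = seq_len(n_layers(series))) {
  stopifnot(inherits(series, "ftir_series"))
  layers <- as.integer(layers)
  if (length(layers) == 0) stop("empty layer selection")
  if (any(layers < 1 | layers > n_layers(series))) {
    stop("layer index out of range")
  }
  ftir_spectrum(series$wavenumbers,
                rowMeans(series$absorbance[, layers, drop = FALSE]))
}

#' Smoothed second derivative of a spectrum
#'
#' Savitzky-Golay convention: a polynomial of order `polyorder` is fit in a
#' sliding window of `window` points and its second derivative evaluated at
#' the centre, scaled by the (uniform) grid step so the result is
#' d^2 A / d nu^2 in AU cm^2. Direction of the stored grid does not matter
#' for an even-order derivative.
#'
#' @param spectrum An `ftir_spectrum` on a uniform grid.
#' @param window Odd window length in points (> `polyorder`).
#' @param polyorder Polynomial order (default 3).
#' @return An `ftir_spectrum` holding the second derivative.
#' @export
second_derivative <- function(spectrum, window = 11, polyorder = 3) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  n <- length(spectrum$wavenumbers)
  if (n < window) stop("window too large for spectrum")
  steps <- diff(spectrum$wavenumbers)
  if (max(abs(abs(steps) - abs(steps[1]))) > 1e-6 * abs(steps[1])) {
    stop("second_derivative requires a uniform wavenumber grid")
  }
  d2 <- signal::sgolayfilt(spectrum$absorbance, p = polyorder, n = window,
                           m = 2, ts = abs(steps[1]))
  ftir_spectrum(spectrum$wavenumbers, d2)
}
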