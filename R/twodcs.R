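#' Dynamic spectra for two-dimensional correlation analysis
#'
#' Subtracts a reference spectrum from every layer of a depth series. The
#' reference is the depth-mean spectrum (the standard convention for
#' generalized two-dimensional correlation spectroscopy), so every
#' wavenumber column of the dynamic matrix has zero mean. Optional per-layer
#' L2 (unit-vector) normalization is applied before the subtraction.
#'
#' @param series An `ftir_series` with at least 3 layers.
#' @param normalize Logical; normalize each layer to unit L2 norm first
#'   (default `FALSE`).
#' @return An object of class `dynamic_spectra`: `matrix` (layers m x
#'   wavenumbers n), `reference` (`ftir_spectrum`), `wavenumbers`, `m`,
#'   `normalized`.
#' @export
dynamic_spectra <- function(series, normalize = FALSE) {
  stopifnot(inherits(series, "ftir_series"))
  m <- n_layers(series)
  if (m < 3) stop("two-dimensional correlation needs at least 3 layers")
  y <- t(series$absorbance)            # m x n
  if (normalize) {
    nrm <- sqrt(rowSums(y^2))
    if (any(nrm == 0)) stop("cannot L2-normalize an all-zero layer")
    y <- y / nrm
  }
  ref <- colMeans(y)
  dyn <- sweep(y, 2, ref)
  structure(list(matrix = dyn,
                 reference = ftir_spectrum(series$wavenumbers, ref),
                 wavenumbers = series$wavenumbers, m = m,
                 normalized = normalize),
            class = "dynamic_spectra")
}

#' Synchronous correlation map
#'
#' Phi(nu1, nu2) = 1/(m-1) * sum_j ytilde_j(nu1) * ytilde_j(nu2): the sample
#' covariance of the dynamic intensities across the perturbation (depth)
#' axis. Symmetric, with the per-wavenumber variance on the diagonal.
#'
#' @param dyn A `dynamic_spectra` object.
#' @return An n x n numeric matrix with wavenumber dimnames.
#' @export
synchronous_map <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_spectra"))
  phi <- crossprod(dyn$matrix) / (dyn$m - 1)
  dimnames(phi) <- list(dyn$wavenumbers, dyn$wavenumbers)
  phi
}

#' Hilbert-Noda transformation matrix
#'
#' N[j, k] = 0 when j = k and 1 / (pi * (k - j)) otherwise; the discrete
#' Hilbert transform kernel used to form the asynchronous correlation map.
#'
#' @param m Number of perturbation points (layers), at least 2.
#' @return An antisymmetric m x m matrix.
#' @export
hilbert_noda_matrix <- function(m) {
  m <- as.integer(m)
  if (m < 2) stop("m must be at least 2")
  j <- matrix(seq_len(m), m, m)
  k <- t(j)
  n <- 1 / (pi * (k - j))
  n[j == k] <- 0
  n
}

#' Asynchronous correlation map
#'
#' Psi(nu1, nu2) = 1/(m-1) * sum_j ytilde_j(nu1) * sum_k N[j,k] ytilde_k(nu2)
#' with N the Hilbert-Noda matrix. Antisymmetric with zero diagonal; its
#' cross-peaks capture out-of-phase (sequential) intensity changes along the
#' perturbation.
#'
#' @param dyn A `dynamic_spectra` object.
#' @return An n x n numeric matrix with wavenumber dimnames.
#' @export
asynchronous_map <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_spectra"))
  nmat <- hilbert_noda_matrix(dyn$m)
  psi <- crossprod(dyn$matrix, nmat %*% dyn$matrix) / (dyn$m - 1)
  dimnames(psi) <- list(dyn$wavenumbers, dyn$wavenumbers)
  psi
}

#' Synchronous and asynchronous maps of a depth series
#'
#' @param series An `ftir_series` (>= 3 layers).
#' @param normalize Passed to [dynamic_spectra()].
#' @return An object of class `correlation_maps`: `sync`, `async`, `grid`,
#'   `m`, `normalized`.
#' @export
correlation_maps <- function(series, normalize = FALSE) {
  dyn <- dynamic_spectra(series, normalize = normalize)
  structure(list(sync = synchronous_map(dyn),
                 async = asynchronous_map(dyn),
                 grid = dyn$wavenumbers, m = dyn$m,
                 normalized = dyn$normalized),
            class = "correlation_maps")
}

#' @export
print.correlation_maps <- function(x, ...) {
  cat(sprintf("<correlation_maps> %d x %d grid, m = %d layers\n",
              length(x$grid), length(x$grid), x$m))
  invisible(x)
}

#' Extract a cross-peak from correlation maps
#'
#' Reads Phi and Psi at the extremum of |Phi| within a rectangular window
#' around the requested (nu1, nu2) coordinates - nearest-grid semantics, no
#' interpolation. With `window = 0` the exact grid point is used. The
#' full-map |Phi| and |Psi| maxima are recorded so sign calls can be
#' threshold-gated relative to the map scale.
#'
#' @param maps A `correlation_maps` object.
#' @param nu1 First (row) wavenumber, default 1338 cm^-1 (collagen).
#' @param nu2 Second (column) wavenumber, default 1064 cm^-1 (proteoglycan).
#' @param window Half-width of the search window in cm^-1 (default 8).
#' @return An object of class `cross_peak`: `nu1`, `nu2` (grid coordinates
#'   actually used), `phi`, `psi`, `window`, `phi_scale`, `psi_scale`.
#' @export
extract_cross_peak <- function(maps, nu1 = 1338, nu2 = 1064, window = 8) {
  stopifnot(inherits(maps, "correlation_maps"))
  rows <- which(abs(maps$grid - nu1) <= window + 1e-9)
  cols <- which(abs(maps$grid - nu2) <= window + 1e-9)
  if (window == 0) {
    rows <- which.min(abs(maps$grid - nu1))
    cols <- which.min(abs(maps$grid - nu2))
    if (abs(maps$grid[rows] - nu1) > 1e-6 || abs(maps$grid[cols] - nu2) > 1e-6) {
      stop("requested coordinates not on the grid (window = 0)")
    }
  }
  if (length(rows) == 0 || length(cols) == 0) {
    stop("cross-peak window falls off the wavenumber grid")
  }
  sub <- maps$sync[rows, cols, drop = FALSE]
  idx <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)
  # deterministic tie-break: first in column-major order
  i <- idx[1, 1]; j <- idx[1, 2]
  structure(list(nu1 = maps$grid[rows[i]], nu2 = maps$grid[cols[j]],
                 phi = maps$sync[rows[i], cols[j]],
                 psi = maps$async[rows[i], cols[j]],
                 window = window,
                 phi_scale = max(abs(maps$sync)),
                 psi_scale = max(abs(maps$async))),
            class = "cross_peak")
}

#' @export
print.cross_peak <- function(x, ...) {
  cat(sprintf("<cross_peak> (%g, %g) cm^-1: phi = %.4g, psi = %.4g\n",
              x$nu1, x$nu2, x$phi, x$psi))
  invisible(x)
}

#' Sequencing call from Noda's sign rules
#'
#' Interprets a synchronous/asynchronous cross-peak pair at (nu1, nu2): a
#' positive synchronous value means the two intensities change in the same
#' direction along the perturbation ("same"), a negative one in opposite
#' directions. When the synchronous and asynchronous signs agree, the
#' intensity change at nu1 occurs before that at nu2; when they differ, nu1
#' changes after nu2. Sign calls are threshold-gated: |psi| below
#' `psi_threshold` times the map |Psi| maximum yields `in_phase`, |phi|
#' below the analogous phi gate yields `indeterminate`.
#'
#' @param cp A `cross_peak`.
#' @param phi_threshold,psi_threshold Relative thresholds (default 1e-3 of
#'   the respective full-map absolute maximum).
#' @return An object of class `sequencing_call`: `direction` (`"same"`,
#'   `"opposite"` or `NA` when indeterminate), `order` (`"nu1_before_nu2"`,
#'   `"nu1_after_nu2"`, `"in_phase"`, `"indeterminate"`) and `rationale`.
#' @export
sequencing_call <- function(cp, phi_threshold = 1e-3, psi_threshold = 1e-3) {
  stopifnot(inherits(cp, "cross_peak"))
  # gates are relative to each map's own maximum, with a numerical-zero
  # floor tied to the synchronous scale: when the whole asynchronous map is
  # zero to rounding error (perfectly in-phase data), its maximum is noise
  # and cannot serve as a scale
  phi_gate <- phi_threshold * cp$phi_scale
  psi_gate <- max(psi_threshold * cp$psi_scale, 1e-9 * cp$phi_scale)
  rationale <- sprintf("phi = %.4g (gate %.3g), psi = %.4g (gate %.3g)",
                       cp$phi, phi_gate, cp$psi, psi_gate)
  if (abs(cp$phi) <= phi_gate) {
    out <- list(direction = NA_character_, order = "indeterminate")
  } else {
    direction <- if (cp$phi > 0) "same" else "opposite"
    if (abs(cp$psi) <= psi_gate) {
      out <- list(direction = direction, order = "in_phase")
    } else if (sign(cp$phi) * sign(cp$psi) > 0) {
      out <- list(direction = direction, order = "nu1_before_nu2")
    } else {
      out <- list(direction = direction, order = "nu1_after_nu2")
    }
  }
  structure(c(out, list(rationale = rationale)), class = "sequencing_call")
}

#' @export
print.sequencing_call <- function(x, ...) {
  cat(sprintf("<sequencing_call> direction = %s, order = %s (%s)\n",
              x$direction, x$order, x$rationale))
  invisible(x)
}

#' Write a correlation map as a CSV matrix
#'
#' @param map Square matrix from [synchronous_map()] / [asynchronous_map()]
#'   or one element of [correlation_maps()].
#' @param path Output path; wavenumbers become row and column headers.
#' @return `path`, invisibly.
#' @export
write_correlation_map <- function(map, path) {
  df <- data.frame(wavenumber = as.numeric(rownames(map)), map,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
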