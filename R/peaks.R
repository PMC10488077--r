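#' Define a spectral band
#'
#' A band ties a named tissue component to a wavenumber region: `center` is
#' the nominal band position, `search_window` the interval in which a fitted
#' component is attributed to the band, and `region` the interval used for
#' curve fitting. For area integration a narrower `area_window` may be given
#' (used for the proteoglycan band, whose search window spans the whole
#' carbohydrate region).
#'
#' @param name Band label, e.g. `"collagen"`, `"pg"`, `"amide_ii"`.
#' @param center Nominal centre (cm^-1).
#' @param search_window Length-2 interval containing `center`.
#' @param region Length-2 fitting interval containing `search_window`.
#' @param area_window Optional length-2 interval used by [band_area()];
#'   defaults to `search_window`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, center, search_window, region,
                            area_window = NULL) {
  search_window <- sort(as.numeric(search_window))
  region <- sort(as.numeric(region))
  if (center < search_window[1] || center > search_window[2]) {
    stop("center must lie inside search_window")
  }
  if (search_window[1] < region[1] || search_window[2] > region[2]) {
    stop("search_window must lie inside region")
  }
  if (is.null(area_window)) area_window <- search_window
  structure(list(name = name, center = center,
                 search_window = search_window, region = region,
                 area_window = sort(as.numeric(area_window))),
            class = "band_definition")
}

#' Default band definitions for corneal stroma FTIR spectra
#'
#' Collagen at 1338 cm^-1 (CH2 wagging of proline side chains), the sulfated
#' proteoglycan indicator at 1064 cm^-1 (symmetric -SO3 stretch) inside the
#' carbohydrate region 984-1140 cm^-1, and the amide II internal reference at
#' 1550 cm^-1 (N-H bending). Search windows default to +/-20 cm^-1 around
#' 1338 and 1550; for the proteoglycan band the search window is the whole
#' carbohydrate region while the default area attribution is the
#' 1064-centred components (+/-20 cm^-1).
#'
#' @return Named list of `band_definition` objects.
#' @export
default_band_definitions <- function() {
  list(
    collagen = band_definition("collagen", 1338, c(1318, 1358), c(1288, 1388)),
    pg = band_definition("pg", 1064, c(984, 1140), c(984, 1140),
                         area_window = c(1044, 1084)),
    amide_ii = band_definition("amide_ii", 1550, c(1530, 1570), c(1480, 1620))
  )
}

#' Second-derivative guided initial peak candidates
#'
#' Candidate band positions are the local minima of the smoothed second
#' derivative (a Gaussian band has a second-derivative minimum at its
#' centre) whose depth exceeds `prominence` times the maximum absolute
#' second derivative. Every supplied band definition is guaranteed a
#' candidate inside its search window: if none is detected, one is inserted
#' at the window centre and flagged. Ties are broken toward lower wavenumber.
#'
#' @param second_deriv `ftir_spectrum` holding the second derivative,
#'   typically restricted to (or computed over) the fitting region.
#' @param band_defs Optional list of `band_definition` objects.
#' @param prominence Fraction of `max(|d2|)` a minimum must reach (default
#'   0.02).
#' @return Data frame with columns `center`, `depth` (second-derivative
#'   value, `NA` for inserted candidates) and `inserted` (logical flag).
#' @export
pick_initial_peaks <- function(second_deriv, band_defs = NULL,
                               prominence = 0.02) {
  stopifnot(inherits(second_deriv, "ftir_spectrum"))
  wn <- second_deriv$wavenumbers
  d2 <- second_deriv$absorbance
  n <- length(d2)
  cand_idx <- integer(0)
  # a flat spectrum filters to rounding noise, not to structure
  if (n >= 3 && max(abs(d2)) > 1e4 * .Machine$double.eps) {
    thr <- -prominence * max(abs(d2))
    i <- 2:(n - 1)
    is_min <- d2[i] < d2[i - 1] & d2[i] <= d2[i + 1] & d2[i] < thr
    cand_idx <- i[is_min]
  }
  # tie-break toward lower wavenumber: for plateaus the <=/< pair above keeps
  # the first point scanned; reorder so lower wavenumbers win when equal
  peaks <- data.frame(center = wn[cand_idx], depth = d2[cand_idx],
                      inserted = rep(FALSE, length(cand_idx)))
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  for (bd in band_defs) {
    inside <- peaks$center >= bd$search_window[1] &
      peaks$center <= bd$search_window[2]
    if (!any(inside)) {
      peaks <- rbind(peaks, data.frame(center = mean(bd$search_window),
                                       depth = NA_real_, inserted = TRUE))
    }
  }
  rownames(peaks) <- NULL
  peaks
}

#' Fit a Gaussian-sum band model to a spectral region
#'
#' The model is a sum of Gaussian components plus a linear baseline fit
#' jointly over the region by bounded Levenberg-Marquardt least squares.
#' Component centres are constrained to the search window of the band they
#' start in (when `band_defs` is given) or to the region otherwise;
#' amplitudes are non-negative and widths positive. Non-convergence is
#' flagged in the diagnostics, never silent.
#'
#' @param spectrum An `ftir_spectrum`.
#' @param region Length-2 wavenumber interval to fit.
#' @param initial_peaks Data frame with a `center` column (e.g. from
#'   [pick_initial_peaks()]); an optional `amplitude` column overrides the
#'   data-driven amplitude guess.
#' @param band_defs Optional list of `band_definition` objects used for
#'   centre bounds.
#' @param init_sigma Initial component width guess in cm^-1 (default 8).
#' @param max_components Cap on the number of components (default 6); the
#'   deepest second-derivative candidates are kept.
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 500).
#' @return An object of class `peak_model` with elements `components`
#'   (data frame: center, amplitude, sigma), `baseline` (slope, intercept,
#'   reference wavenumber), `region`, and `diagnostics` (residual RMS,
#'   convergence flag, iteration count).
#' @export
fit_peaks <- function(spectrum, region, initial_peaks, band_defs = NULL,
                      init_sigma = 8, max_components = 6, max_iter = 500) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  region <- sort(as.numeric(region))
  sel <- spectrum$wavenumbers >= region[1] & spectrum$wavenumbers <= region[2]
  if (sum(sel) < 5) stop("fitting region contains too few grid points")
  wn <- spectrum$wavenumbers[sel]
  ab <- spectrum$absorbance[sel]
  if (is.null(initial_peaks) || nrow(initial_peaks) < 1) {
    stop("at least one initial peak is required")
  }
  pk <- initial_peaks[initial_peaks$center >= region[1] &
                        initial_peaks$center <= region[2], , drop = FALSE]
  if (nrow(pk) < 1) stop("no initial peak inside the fitting region")
  if (nrow(pk) > max_components) {
    o <- order(ifelse(is.na(pk$depth), 0, pk$depth))  # deepest (most neg) first
    pk <- pk[o[seq_len(max_components)], , drop = FALSE]
  }
  k <- nrow(pk)
  wn_ref <- mean(wn)
  # baseline guess through the region end points
  i_lo <- which.min(wn); i_hi <- which.max(wn)
  slope0 <- (ab[i_hi] - ab[i_lo]) / (wn[i_hi] - wn[i_lo])
  icpt0 <- ab[i_lo] - slope0 * (wn[i_lo] - wn_ref)
  amp0 <- if (!is.null(pk$amplitude)) {
    pmax(pk$amplitude, 1e-8)
  } else {
    base_at <- icpt0 + slope0 * (pk$center - wn_ref)
    pmax(stats::approx(wn, ab, xout = pk$center, rule = 2)$y - base_at, 1e-6)
  }
  lower_c <- rep(region[1], k)
  upper_c <- rep(region[2], k)
  if (!is.null(band_defs)) {
    for (bd in band_defs) {
      inside <- pk$center >= bd$search_window[1] &
        pk$center <= bd$search_window[2]
      lower_c[inside] <- pmax(lower_c[inside], bd$search_window[1])
      upper_c[inside] <- pmin(upper_c[inside], bd$search_window[2])
    }
  }
  par0 <- c(rbind(pk$center, amp0, rep(init_sigma, k)), slope0, icpt0)
  lower <- c(rbind(lower_c, rep(0, k), rep(1, k)), -Inf, -Inf)
  upper <- c(rbind(upper_c, rep(Inf, k), rep(100, k)), Inf, Inf)
  model_fn <- function(par) {
    m <- par[3 * k + 2] + par[3 * k + 1] * (wn - wn_ref)
    for (j in seq_len(k)) {
      c_j <- par[3 * (j - 1) + 1]
      a_j <- par[3 * (j - 1) + 2]
      s_j <- par[3 * (j - 1) + 3]
      m <- m + a_j * exp(-(wn - c_j)^2 / (2 * s_j^2))
    }
    m
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(par) ab - model_fn(par),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-12, ptol = 1e-10))
  par <- fit$par
  comps <- data.frame(
    center = par[3 * (seq_len(k) - 1) + 1],
    amplitude = par[3 * (seq_len(k) - 1) + 2],
    sigma = par[3 * (seq_len(k) - 1) + 3])
  comps <- comps[order(comps$center), , drop = FALSE]
  rownames(comps) <- NULL
  resid <- ab - model_fn(par)
  structure(list(
    components = comps,
    baseline = c(slope = unname(par[3 * k + 1]),
                 intercept = unname(par[3 * k + 2]), wn_ref = wn_ref),
    region = region,
    diagnostics = list(rms = sqrt(mean(resid^2)),
                       converged = fit$info %in% 1:4,
                       info = fit$info, niter = fit$niter),
    wavenumbers = wn, fitted = model_fn(par), observed = ab),
    class = "peak_model")
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf("<peak_model> %d components on [%g, %g] cm^-1, rms %.3g, %s\n",
              nrow(x$components), x$region[1], x$region[2],
              x$diagnostics$rms,
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  print(x$components)
  invisible(x)
}

#' Analytic band area from a fitted model
#'
#' Sum of the closed-form Gaussian areas amplitude * sigma * sqrt(2*pi) over
#' the components whose centres lie inside the band's area window (baseline
#' excluded).
#'
#' @param peak_model A `peak_model` from [fit_peaks()].
#' @param band_def A `band_definition`.
#' @param window Either `"area"` (default: the band's `area_window`) or
#'   `"search"` to integrate every component in the search window - for the
#'   proteoglycan band this switches between the 1064-centred components and
#'   the whole carbohydrate region.
#' @return Band area in AU cm^-1.
#' @export
band_area <- function(peak_model, band_def, window = c("area", "search")) {
  stopifnot(inherits(peak_model, "peak_model"),
            inherits(band_def, "band_definition"))
  window <- match.arg(window)
  w <- if (window == "area") band_def$area_window else band_def$search_window
  comps <- peak_model$components
  inside <- comps$center >= w[1] & comps$center <= w[2]
  if (!any(inside)) {
    stop(sprintf("no fitted component inside the %s band window [%g, %g]",
                 band_def$name, w[1], w[2]))
  }
  sum(comps$amplitude[inside] * comps$sigma[inside] * sqrt(2 * pi))
}

#' Relative collagen and proteoglycan content
#'
#' The ratios collagen/amide II and PG/amide II of fitted band areas, the
#' amide II band acting as internal protein reference; the ratios are
#' scale-free, so absolute absorbance calibration cancels.
#'
#' @param collagen_area,pg_area,amide_ii_area Band areas (AU cm^-1).
#' @param region_label Optional label (e.g. `"Sc-ACA"`) attached by the
#'   caller.
#' @return An object of class `composition_result` with `collagen_ratio`,
#'   `pg_ratio` and `region_label`.
#' @export
relative_content <- function(collagen_area, pg_area, amide_ii_area,
                             region_label = NA_character_) {
  if (!is.finite(amide_ii_area) || amide_ii_area == 0) {
    stop("amide II area is zero or missing: ratios undefined")
  }
  if (collagen_area < 0 || pg_area < 0 || amide_ii_area < 0) {
    stop("band areas must be non-negative")
  }
  structure(list(collagen_ratio = collagen_area / amide_ii_area,
                 pg_ratio = pg_area / amide_ii_area,
                 region_label = region_label),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("<composition_result> %s collagen/amideII = %.4f, PG/amideII = %.4f\n",
              ifelse(is.na(x$region_label), "", x$region_label),
              x$collagen_ratio, x$pg_ratio))
  invisible(x)
}

#' Full composition workup of one spectrum
#'
#' Convenience chain: for each band's fitting region, compute the smoothed
#' second derivative, pick initial peaks, fit the Gaussian-sum model and
#' extract the band area; then form the collagen/amide II and PG/amide II
#' ratios.
#'
#' @param spectrum An `ftir_spectrum` (typically a coadded ROI spectrum).
#' @param band_defs Band definitions (default [default_band_definitions()]).
#' @param region_label Label forwarded to [relative_content()].
#' @param pg_window `"area"` or `"search"`, see [band_area()].
#' @param sg_window,sg_polyorder Savitzky-Golay settings for the
#'   second-derivative peak picking.
#' @return List with `composition` (a `composition_result`), `areas`,
#'   `models` (one `peak_model` per fitted region) and `converged`.
#' @export
fit_composition <- function(spectrum, band_defs = default_band_definitions(),
                            region_label = NA_character_,
                            pg_window = "area",
                            sg_window = 11, sg_polyorder = 3) {
  models <- list()
  areas <- numeric(0)
  for (nm in names(band_defs)) {
    bd <- band_defs[[nm]]
    sel <- spectrum$wavenumbers >= bd$region[1] &
      spectrum$wavenumbers <= bd$region[2]
    sub <- ftir_spectrum(spectrum$wavenumbers[sel], spectrum$absorbance[sel])
    d2 <- second_derivative(sub, window = sg_window, polyorder = sg_polyorder)
    pk <- pick_initial_peaks(d2, band_defs = list(bd))
    models[[nm]] <- fit_peaks(sub, bd$region, pk, band_defs = list(bd))
    areas[nm] <- band_area(models[[nm]], bd,
                           window = if (nm == "pg") pg_window else "area")
  }
  comp <- relative_content(areas[["collagen"]], areas[["pg"]],
                           areas[["amide_ii"]], region_label = region_label)
  list(composition = comp, areas = areas, models = models,
       converged = all(vapply(models, function(m) m$diagnostics$converged,
                              logical(1))))
}
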