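#' Default simulated band set
#'
#' The three bands the composition analysis relies on: collagen at
#' 1338 cm^-1, the proteoglycan indicator at 1064 cm^-1 and the amide II
#' reference at 1550 cm^-1, with plausible widths and base amplitudes.
#'
#' @return Data frame with columns `name`, `center`, `sigma`, `amplitude`.
#' @export
default_sim_bands <- function() {
  data.frame(name = c("collagen", "pg", "amide_ii"),
             center = c(1338, 1064, 1550),
             sigma = c(8, 10, 12),
             amplitude = c(0.5, 0.3, 0.8))
}

#' Configuration for the depth-series spectral generator
#'
#' Defines a multi-band Gaussian spectrum whose band amplitudes follow
#' depth-dependent profiles across `n_layers` stromal layers. Profiles are
#' `constant`, `linear` (relative amplitude `lo` at layer 1 to `hi` at layer
#' `n_layers`) or `sigmoid` (logistic transition of midpoint `midpoint`
#' layers and steepness `rate`). `lag_layers` shifts the proteoglycan band's
#' sigmoid midpoint relative to the collagen band's: positive values make
#' the proteoglycan transition trail (collagen leads), negative values make
#' it lead.
#'
#' @param wavenumber_range Length-2 descending range in cm^-1 (default
#'   4000 to 748).
#' @param step Grid step in cm^-1 (default 4).
#' @param n_layers Number of depth layers (default 25), at least 3.
#' @param bands Data frame as in [default_sim_bands()].
#' @param depth_profiles Named list (by band name) of profile specs, each a
#'   list with `type` and parameters (`lo`, `hi`, `midpoint`, `rate`).
#'   Bands without an entry are constant. `NULL` gives sigmoid profiles for
#'   collagen and proteoglycan (midpoint mid-stack, `lo` 0.7, `hi` 1.3,
#'   `rate` 2) and a constant amide II.
#' @param lag_layers Signed layer shift of the proteoglycan transition
#'   relative to collagen (default 0).
#' @param noise_sd Gaussian noise standard deviation in absorbance units
#'   (default 0).
#' @param baseline Length-2 numeric `c(slope, intercept)` of a linear
#'   baseline in the wavenumber (default zero).
#' @param seed Integer RNG seed.
#' @return An object of class `spectral_sim_config`.
#' @export
spectral_sim_config <- function(wavenumber_range = c(4000, 748), step = 4,
                                n_layers = 25, bands = default_sim_bands(),
                                depth_profiles = NULL, lag_layers = 0,
                                noise_sd = 0,
                                baseline = c(slope = 0, intercept = 0),
                                seed = 1) {
  if (n_layers < 3) stop("n_layers must be at least 3")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  lo <- min(wavenumber_range); hi <- max(wavenumber_range)
  if (any(bands$center < lo | bands$center > hi)) {
    stop("all band centers must lie inside wavenumber_range")
  }
  if (is.null(depth_profiles)) {
    mid <- (n_layers + 1) / 2
    depth_profiles <- list()
    if ("collagen" %in% bands$name) {
      depth_profiles$collagen <- list(type = "sigmoid", lo = 0.7, hi = 1.3,
                                      midpoint = mid, rate = 2)
    }
    if ("pg" %in% bands$name) {
      depth_profiles$pg <- list(type = "sigmoid", lo = 0.7, hi = 1.3,
                                midpoint = mid, rate = 2)
    }
  }
  structure(list(wavenumber_range = c(hi, lo), step = step,
                 n_layers = as.integer(n_layers), bands = bands,
                 depth_profiles = depth_profiles,
                 lag_layers = lag_layers, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "spectral_sim_config")
}

profile_value <- function(profile, layer, n_layers) {
  if (is.null(profile)) return(rep(1, length(layer)))
  switch(profile$type,
         constant = rep(1, length(layer)),
         linear = profile$lo + (profile$hi - profile$lo) *
           (layer - 1) / (n_layers - 1),
         sigmoid = profile$lo + (profile$hi - profile$lo) /
           (1 + exp(-(layer - profile$midpoint) / profile$rate)),
         stop("unknown depth profile type: ", profile$type))
}

#' Generate a depth-resolved spectral series with known ground truth
#'
#' Renders `n_layers` spectra on a common descending wavenumber grid: for
#' each layer, each band contributes a Gaussian with amplitude
#' `base amplitude x depth profile(layer)`, on top of a linear baseline and
#' optional i.i.d. Gaussian noise. The proteoglycan band's sigmoid midpoint
#' is shifted by `lag_layers` relative to its specification, planting a
#' known lead/lag between the collagen and proteoglycan depth responses.
#'
#' @param cfg A `spectral_sim_config`.
#' @return List with `series` (`ftir_series`), `ground_truth` (data frame:
#'   `layer`, `band`, `amplitude`) and `config`.
#' @export
generate_depth_series <- function(cfg) {
  stopifnot(inherits(cfg, "spectral_sim_config"))
  set.seed(cfg$seed)
  wn <- seq(cfg$wavenumber_range[1], cfg$wavenumber_range[2], by = -cfg$step)
  layers <- seq_len(cfg$n_layers)
  profiles <- cfg$depth_profiles
  if (!is.null(profiles$pg) && cfg$lag_layers != 0) {
    if (!identical(profiles$pg$type, "sigmoid")) {
      stop("lag_layers requires a sigmoid proteoglycan profile")
    }
    profiles$pg$midpoint <- profiles$pg$midpoint + cfg$lag_layers
  }
  amp <- matrix(NA_real_, cfg$n_layers, nrow(cfg$bands),
                dimnames = list(NULL, cfg$bands$name))
  for (b in seq_len(nrow(cfg$bands))) {
    nm <- cfg$bands$name[b]
    amp[, b] <- cfg$bands$amplitude[b] *
      profile_value(profiles[[nm]], layers, cfg$n_layers)
  }
  base <- cfg$baseline[["intercept"]] + cfg$baseline[["slope"]] * wn
  mat <- matrix(base, length(wn), cfg$n_layers)
  for (b in seq_len(nrow(cfg$bands))) {
    shape <- exp(-(wn - cfg$bands$center[b])^2 / (2 * cfg$bands$sigma[b]^2))
    mat <- mat + outer(shape, amp[, b])
  }
  if (cfg$noise_sd > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), sd = cfg$noise_sd),
                        nrow(mat), ncol(mat))
  }
  gt <- data.frame(layer = rep(layers, times = nrow(cfg$bands)),
                   band = rep(cfg$bands$name, each = cfg$n_layers),
                   amplitude = as.vector(amp))
  list(series = ftir_series(wn, mat), ground_truth = gt, config = cfg)
}
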