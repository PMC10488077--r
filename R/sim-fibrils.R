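#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the uniform circular
#' distribution; very large `kappa` (> 1e8) collapses to the mean direction.
#' Uses the current RNG state.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter, >= 0 (may be `Inf`).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  if (!is.finite(kappa) || kappa > 1e8) return(rep(mu %% (2 * pi), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) break
    }
    u3 <- stats::runif(1)
    out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
  }
  out
}

# axial (undirected) von Mises draw on [0, pi): theta and theta + pi identified
raxial_vonmises <- function(n, mu, kappa) {
  (rvonmises(n, 2 * mu, kappa) / 2) %% pi
}

#' Configuration for the fibril-image generator
#'
#' @param image_size Side of the square image in pixels (default 200).
#' @param n_fibers Number of fibers (default 30; 0 gives a blank image).
#' @param length_mean,length_sd Fiber length distribution in pixels
#'   (defaults 120 and 20; lengths are clipped below at 10 px).
#' @param width_px Fiber stroke width in pixels, >= 1 (default 3).
#' @param orientation_mu Mean axial orientation in radians (default 0).
#' @param orientation_kappa Concentration of the axial von Mises
#'   orientation distribution: `Inf` = perfectly parallel, 0 = isotropic
#'   (default 5).
#' @param curvature_amp Dimensionless bow amplitude: the centerline is
#'   displaced laterally by `curvature_amp * length * sin(pi * s / length)`;
#'   0 gives perfectly straight fibers (default 0.1).
#' @param background_noise_sd Gaussian background noise in 8-bit gray
#'   levels (default 5).
#' @param seed Integer RNG seed.
#' @return An object of class `fibril_sim_config`.
#' @export
fibril_sim_config <- function(image_size = 200, n_fibers = 30,
                              length_mean = 120, length_sd = 20,
                              width_px = 3, orientation_mu = 0,
                              orientation_kappa = 5, curvature_amp = 0.1,
                              background_noise_sd = 5, seed = 1) {
  if (width_px < 1) stop("width_px must be at least 1")
  if (image_size < 16) stop("image_size must be at least 16")
  if (n_fibers < 0) stop("n_fibers must be non-negative")
  if (background_noise_sd < 0) stop("background_noise_sd must be non-negative")
  structure(list(image_size = as.integer(image_size),
                 n_fibers = as.integer(n_fibers),
                 length_mean = length_mean, length_sd = length_sd,
                 width_px = width_px, orientation_mu = orientation_mu,
                 orientation_kappa = orientation_kappa,
                 curvature_amp = curvature_amp,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "fibril_sim_config")
}

# Sample fiber centerline polylines (uses current RNG state). Returns a list
# of two-column matrices (row, col), one per fiber, clipped to the image.
sample_fiber_paths <- function(cfg) {
  size <- cfg$image_size
  paths <- list()
  if (cfg$n_fibers == 0) return(paths)
  thetas <- raxial_vonmises(cfg$n_fibers, cfg$orientation_mu,
                            cfg$orientation_kappa)
  for (f in seq_len(cfg$n_fibers)) {
    len <- max(10, stats::rnorm(1, cfg$length_mean, cfg$length_sd))
    theta <- thetas[f]
    u <- c(cos(theta), sin(theta))      # (x, y) direction
    v <- c(-sin(theta), cos(theta))     # unit normal
    margin <- cfg$width_px + 2
    cx <- stats::runif(1, margin, size - margin)
    cy <- stats::runif(1, margin, size - margin)
    s <- seq(0, len, by = 1)
    disp <- cfg$curvature_amp * len * sin(pi * s / len)
    x <- cx + (s - len / 2) * u[1] + disp * v[1]
    y <- cy + (s - len / 2) * u[2] + disp * v[2]
    inside <- x >= 1.5 & x <= size - 0.5 & y >= 1.5 & y <= size - 0.5
    if (!any(inside)) next
    # keep the longest contiguous run inside the image
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    keep <- starts[best]:ends[best]
    if (length(keep) < 2) next
    paths[[length(paths) + 1]] <- cbind(row = y[keep], col = x[keep])
  }
  paths
}

ground_truth_from_paths <- function(paths, width_px) {
  if (!length(paths)) {
    return(data.frame(fiber_id = integer(0), length_px = numeric(0),
                      width_px = numeric(0), straightness = numeric(0),
                      orientation = numeric(0)))
  }
  rows <- lapply(seq_along(paths), function(f) {
    p <- paths[[f]]
    d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    arc <- sum(d)
    chord <- sqrt((p[nrow(p), 1] - p[1, 1])^2 + (p[nrow(p), 2] - p[1, 2])^2)
    data.frame(fiber_id = f, length_px = arc, width_px = width_px,
               straightness = chord / arc,
               orientation = atan2(p[nrow(p), 1] - p[1, 1],
                                   p[nrow(p), 2] - p[1, 2]) %% pi)
  })
  do.call(rbind, rows)
}

#' Render fiber polylines into a grayscale image
#'
#' Anti-aliased rasterization: each polyline is densified and stamped as a
#' stroke of the given width with a one-pixel linear falloff at the edge;
#' overlapping fibers combine by maximum intensity.
#'
#' @param paths List of two-column (row, col) polyline matrices.
#' @param image_size Side of the square canvas in pixels.
#' @param width_px Stroke width in pixels.
#' @return Numeric matrix in [0, 1].
#' @export
render_fibril_paths <- function(paths, image_size, width_px) {
  size <- as.integer(image_size)
  canvas <- matrix(0, size, size)
  half <- width_px / 2
  r <- ceiling(half + 1)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  for (p in paths) {
    if (nrow(p) < 2) next
    seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    cum <- c(0, cumsum(seg))
    dense_s <- seq(0, cum[length(cum)], by = 0.3)
    y <- stats::approx(cum, p[, 1], xout = dense_s)$y
    x <- stats::approx(cum, p[, 2], xout = dense_s)$y
    py <- round(y); px <- round(x)
    for (k in seq_len(nrow(offs))) {
      iy <- py + offs$di[k]
      ix <- px + offs$dj[k]
      ok <- iy >= 1 & iy <= size & ix >= 1 & ix <= size
      if (!any(ok)) next
      d <- sqrt((iy[ok] - y[ok])^2 + (ix[ok] - x[ok])^2)
      val <- pmin(1, pmax(0, half + 0.5 - d))
      pos <- val > 0
      if (!any(pos)) next
      idx <- cbind(iy[ok][pos], ix[ok][pos])
      v <- val[pos]
      o <- order(v)
      canvas[idx[o, , drop = FALSE]] <-
        pmax(canvas[idx[o, , drop = FALSE]], v[o])
    }
  }
  canvas
}

#' Generate a synthetic fibril image with ground truth
#'
#' Samples fiber centerlines (axial von Mises orientations, Gaussian
#' lengths, sinusoidal bow controlled by `curvature_amp`), records the
#' ground-truth morphometry before rasterization, renders the anti-aliased
#' image and adds background noise.
#'
#' @param cfg A `fibril_sim_config`.
#' @return List with `image` (matrix in [0, 1]), `ground_truth` (data
#'   frame: `fiber_id`, `length_px`, `width_px`, `straightness`,
#'   `orientation`), `paths` (polylines), `foreground` (noise-free logical
#'   stroke mask at half rendered intensity) and `config`.
#' @export
generate_fibril_image <- function(cfg) {
  stopifnot(inherits(cfg, "fibril_sim_config"))
  set.seed(cfg$seed)
  paths <- sample_fiber_paths(cfg)
  img <- render_fibril_paths(paths, cfg$image_size, cfg$width_px)
  fg <- img >= 0.5   # stroke footprint at half intensity (anti-alias fringe excluded)
  if (cfg$background_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img),
                                     sd = cfg$background_noise_sd / 255),
                        nrow(img), ncol(img))
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img,
       ground_truth = ground_truth_from_paths(paths, cfg$width_px),
       paths = paths, foreground = fg, config = cfg)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img Numeric matrix in [0, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fibril_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a grayscale PNG as a numeric matrix
#'
#' @param path PNG path; multi-channel images are averaged to grayscale.
#' @return Numeric matrix in [0, 1].
#' @export
read_fibril_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , seq_len(min(3, dim(x)[3])),
                                        drop = FALSE], c(1, 2), mean)
  x
}
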