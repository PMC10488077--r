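test_that("dynamic spectra center the layers on the depth mean", {
  wn <- seq(1400, 1000, by = -4)
  x <- exp(-(wn - 1200)^2 / 800)
  s <- ftir_series(wn, cbind(x, x, x))
  dyn <- dynamic_spectra(s)
  expect_true(all(dyn$matrix == 0))
  s2 <- ftir_series(wn, cbind(1 * x, 2 * x, 3 * x))
  dyn2 <- dynamic_spectra(s2)
  expect_equal(unname(dyn2$matrix %*% x / sum(x^2))[, 1], c(-1, 0, 1))
  expect_lt(max(abs(colMeans(dyn2$matrix))), 1e-10 * max(abs(s2$absorbance)))
})

test_that("synchronous map equals the hand example and a covariance oracle", {
  # m = 3, ytilde(nu1) = [-1,0,1], ytilde(nu2) = [-2,0,2] -> Phi12 = 2
  wn <- c(1338, 1064)
  s <- ftir_series(wn, rbind(c(0, 1, 2), c(0, 2, 4)))
  phi <- synchronous_map(dynamic_spectra(s))
  expect_equal(phi[1, 2], 2)
  expect_true(all(diag(phi) >= 0))

  set.seed(42)
  mat <- matrix(rnorm(25 * 40), 40, 25)  # 40 wavenumbers x 25 layers
  s2 <- ftir_series(seq(1400, 1244, by = -4), mat)
  phi2 <- synchronous_map(dynamic_spectra(s2))
  # independent two-pass covariance oracle
  y <- t(mat)
  mu <- colMeans(y)
  oracle <- matrix(0, 40, 40)
  for (a in 1:40) for (b in 1:40) {
    oracle[a, b] <- sum((y[, a] - mu[a]) * (y[, b] - mu[b])) / 24
  }
  expect_lt(max(abs(unname(phi2) - oracle)), 1e-10 * max(abs(oracle)))
  expect_equal(unname(phi2), unname(stats::cov(y)), tolerance = 1e-12)
})

test_that("the Hilbert-Noda matrix matches its definition", {
  n2 <- hilbert_noda_matrix(2)
  expect_equal(n2, matrix(c(0, -1 / pi, 1 / pi, 0), 2, 2))
  for (m in c(3, 10, 25)) {
    nm <- hilbert_noda_matrix(m)
    expect_equal(nm + t(nm), matrix(0, m, m))
  }
  # row sums against brute-force harmonic sums
  n25 <- hilbert_noda_matrix(25)
  oracle <- sapply(1:25, function(j) {
    sum(sapply((1:25)[-j], function(k) 1 / (pi * (k - j))))
  })
  expect_equal(rowSums(n25), oracle, tolerance = 1e-12)
})

test_that("asynchronous map is antisymmetric and vanishes for proportional profiles", {
  coefs <- cbind(sin(1:7), 2.5 * sin(1:7))   # nu2 profile = 2.5 x nu1 profile
  s <- coef_series(coefs)
  maps <- correlation_maps(s)
  i1 <- which.min(abs(s$wavenumbers - 1338))
  i2 <- which.min(abs(s$wavenumbers - 1064))
  expect_lt(abs(maps$async[i1, i2]), 1e-12)
  expect_equal(maps$async, -t(maps$async))
  expect_true(all(abs(diag(maps$async)) < 1e-14))

  set.seed(9)
  s2 <- ftir_series(seq(1400, 1324, by = -4), matrix(rnorm(20 * 6), 20, 6))
  psi <- asynchronous_map(dynamic_spectra(s2))
  expect_equal(psi, -t(psi))
})

test_that("maps match a brute-force double-sum evaluation on a lagged series", {
  cfg <- spectral_sim_config(n_layers = 25, lag_layers = 5, noise_sd = 0,
                             wavenumber_range = c(1600, 1000), seed = 1)
  s <- generate_depth_series(cfg)$series
  maps <- correlation_maps(s)
  bf <- brute_force_maps(t(s$absorbance))
  expect_equal(unname(maps$sync), bf$phi, tolerance = 1e-12)
  expect_equal(unname(maps$async), bf$psi, tolerance = 1e-12)
  # both bands increase with depth and collagen leads: phi > 0, psi > 0
  cp <- extract_cross_peak(maps)
  expect_gt(cp$phi, 0)
  expect_gt(cp$phi * cp$psi, 0)
})

test_that("cross-peak extraction honours windows, planting and symmetry", {
  grid <- seq(1400, 1000, by = -4)
  n <- length(grid)
  phi <- matrix(0, n, n, dimnames = list(grid, grid))
  psi <- matrix(0, n, n, dimnames = list(grid, grid))
  i1 <- which(grid == 1336); i2 <- which(grid == 1068)
  phi[i1, i2] <- phi[i2, i1] <- 5
  psi[i1, i2] <- 3; psi[i2, i1] <- -3
  maps <- structure(list(sync = phi, async = psi, grid = grid, m = 25,
                         normalized = FALSE), class = "correlation_maps")
  cp <- extract_cross_peak(maps, 1338, 1064, window = 8)
  expect_equal(cp$nu1, 1336)
  expect_equal(cp$nu2, 1068)
  expect_equal(cp$phi, 5)
  expect_equal(cp$psi, 3)
  # swapped coordinates return (phi, -psi)
  cp2 <- extract_cross_peak(maps, 1064, 1338, window = 8)
  expect_equal(cp2$phi, cp$phi)
  expect_equal(cp2$psi, -cp$psi)
  # degenerate window reads the exact grid point
  cp0 <- extract_cross_peak(maps, 1336, 1068, window = 0)
  expect_equal(cp0$phi, phi[i1, i2])
  expect_equal(cp0$psi, psi[i1, i2])
  # requested coordinate must be a grid point when the window is 0
  expect_error(extract_cross_peak(maps, 1338, 1064, window = 0), "not on the grid")
  expect_error(extract_cross_peak(maps, 900, 1064, window = 4), "off")
})

test_that("sequencing calls follow the synchronous/asynchronous sign rules", {
  mk <- function(phi, psi) {
    structure(list(nu1 = 1338, nu2 = 1064, phi = phi, psi = psi, window = 8,
                   phi_scale = 1, psi_scale = 1), class = "cross_peak")
  }
  # same signs: nu1 changes before nu2; opposite: after
  expect_equal(sequencing_call(mk(0.5, 0.3))$order, "nu1_before_nu2")
  expect_equal(sequencing_call(mk(0.5, 0.3))$direction, "same")
  expect_equal(sequencing_call(mk(0.5, -0.3))$order, "nu1_after_nu2")
  expect_equal(sequencing_call(mk(-0.5, 0.3))$order, "nu1_after_nu2")
  expect_equal(sequencing_call(mk(-0.5, 0.3))$direction, "opposite")
  expect_equal(sequencing_call(mk(-0.5, -0.3))$order, "nu1_before_nu2")
  # threshold gates
  expect_equal(sequencing_call(mk(0.5, 1e-5))$order, "in_phase")
  expect_equal(sequencing_call(mk(1e-5, 0.3))$order, "indeterminate")
})

test_that("scaling all layers rescales the maps by c^2 and keeps the calls", {
  cfg <- spectral_sim_config(lag_layers = 3, noise_sd = 0,
                             wavenumber_range = c(1600, 1000), seed = 2)
  s <- generate_depth_series(cfg)$series
  m1 <- correlation_maps(s)
  s2 <- ftir_series(s$wavenumbers, 4 * s$absorbance)
  m2 <- correlation_maps(s2)
  expect_equal(m2$sync, 16 * m1$sync, tolerance = 1e-12)
  expect_equal(m2$async, 16 * m1$async, tolerance = 1e-12)
  expect_equal(sequencing_call(extract_cross_peak(m2))$order,
               sequencing_call(extract_cross_peak(m1))$order)
})

test_that("per-layer normalization undoes global layer scale factors", {
  coefs <- cbind(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  s <- coef_series(coefs)
  scales <- c(1, 1.5, 0.7, 2, 1.2)
  s_scaled <- ftir_series(s$wavenumbers,
                          sweep(s$absorbance, 2, scales, `*`))
  m_ref <- correlation_maps(s, normalize = TRUE)
  m_scl <- correlation_maps(s_scaled, normalize = TRUE)
  expect_equal(m_ref$sync, m_scl$sync, tolerance = 1e-12)
  expect_equal(m_ref$async, m_scl$async, tolerance = 1e-12)
})
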