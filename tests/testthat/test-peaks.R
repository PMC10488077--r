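test_that("initial peak picking finds noiseless band centers and flags fallbacks", {
  wn <- seq(1400, 1280, by = -4)
  bd <- default_band_definitions()$collagen
  sp <- ftir_spectrum(wn, 0.5 * exp(-(wn - 1338)^2 / (2 * 9^2)))
  pk <- pick_initial_peaks(second_derivative(sp), band_defs = list(bd))
  expect_false(any(pk$inserted))
  expect_true(min(abs(pk$center - 1338)) <= 4)

  flat <- ftir_spectrum(wn, rep(0.2, length(wn)))
  pkf <- pick_initial_peaks(second_derivative(flat), band_defs = list(bd))
  expect_true(all(pkf$inserted))
  expect_equal(nrow(pkf), 1)
  expect_equal(pkf$center, mean(bd$search_window))
})

test_that("candidate set matches a brute-force local-minima scan", {
  wn <- seq(1650, 950, by = -4)
  ab <- 0.5 * exp(-(wn - 1338)^2 / (2 * 8^2)) +
    0.3 * exp(-(wn - 1064)^2 / (2 * 10^2)) +
    0.8 * exp(-(wn - 1550)^2 / (2 * 12^2))
  d2 <- second_derivative(ftir_spectrum(wn, ab))
  pk <- pick_initial_peaks(d2)
  # exhaustive scan oracle over the same derivative values
  v <- d2$absorbance
  thr <- -0.02 * max(abs(v))
  idx <- which(vapply(2:(length(v) - 1), function(i) {
    v[i] < v[i - 1] && v[i] <= v[i + 1] && v[i] < thr
  }, logical(1))) + 1
  expect_setequal(pk$center, d2$wavenumbers[idx])
})

test_that("a single noiseless Gaussian is recovered to high precision", {
  wn <- seq(1400, 1280, by = -4)
  truth <- c(center = 1338, amplitude = 0.5, sigma = 10)
  sp <- ftir_spectrum(wn, truth["amplitude"] *
                        exp(-(wn - truth["center"])^2 / (2 * truth["sigma"]^2)))
  bd <- default_band_definitions()$collagen
  pk <- pick_initial_peaks(second_derivative(sp), band_defs = list(bd))
  fit <- fit_peaks(sp, bd$region, pk, band_defs = list(bd))
  expect_true(fit$diagnostics$converged)
  expect_lt(abs(fit$components$center - 1338), 1e-6)
  expect_lt(abs(fit$components$amplitude - 0.5), 1e-6)
  expect_lt(abs(fit$components$sigma - 10), 1e-6)
  expect_lt(fit$diagnostics$rms, 1e-8 * 0.5)
})

test_that("overlapping Gaussian areas are recovered within 2% at SNR 100", {
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    wn <- seq(1650, 1450, by = -2)
    a1 <- 0.6; a2 <- 0.4; s12 <- 12
    ab <- a1 * exp(-(wn - 1550)^2 / (2 * s12^2)) +
      a2 * exp(-(wn - 1520)^2 / (2 * s12^2)) +
      rnorm(length(wn), sd = a1 / 100)
    sp <- ftir_spectrum(wn, ab)
    b1 <- band_definition("b1", 1550, c(1535, 1565), c(1460, 1640))
    b2 <- band_definition("b2", 1520, c(1505, 1535), c(1460, 1640))
    pk <- pick_initial_peaks(second_derivative(sp), band_defs = list(b1, b2))
    fit <- fit_peaks(sp, c(1460, 1640), pk, band_defs = list(b1, b2))
    c(abs(band_area(fit, b1) / (a1 * s12 * sqrt(2 * pi)) - 1),
      abs(band_area(fit, b2) / (a2 * s12 * sqrt(2 * pi)) - 1))
  })
  expect_lt(median(errs), 0.02)
})

test_that("the fit is stable to perturbed initial guesses", {
  wn <- seq(1400, 1280, by = -4)
  sp <- ftir_spectrum(wn, 0.5 * exp(-(wn - 1338)^2 / (2 * 10^2)) +
                        0.02 + 1e-4 * (wn - 1340))
  bd <- default_band_definitions()$collagen
  base <- fit_peaks(sp, bd$region, data.frame(center = 1338),
                    band_defs = list(bd))
  for (d in c(-5, 5)) {
    alt <- fit_peaks(sp, bd$region, data.frame(center = 1338 + d),
                     band_defs = list(bd))
    expect_equal(alt$components$center, base$components$center,
                 tolerance = 1e-4)
    expect_equal(alt$components$amplitude, base$components$amplitude,
                 tolerance = 1e-4)
  }
})

test_that("band areas follow the closed form and match quadrature", {
  wn <- seq(1400, 1280, by = -0.5)
  bd <- default_band_definitions()$collagen
  mk <- function(amp) {
    pk <- data.frame(center = 1338)
    fit_peaks(ftir_spectrum(wn, amp * exp(-(wn - 1338)^2 / 2)), bd$region,
              pk, band_defs = list(bd), init_sigma = 2)
  }
  f1 <- mk(1)
  expect_equal(band_area(f1, bd), sqrt(2 * pi), tolerance = 1e-6)
  f2 <- mk(2)
  expect_equal(band_area(f2, bd), 2 * band_area(f1, bd), tolerance = 1e-6)
  # quadrature oracle on the isolated fitted component
  comp <- f1$components
  fine <- seq(comp$center - 40, comp$center + 40, by = 0.01)
  y <- comp$amplitude * exp(-(fine - comp$center)^2 / (2 * comp$sigma^2))
  trapz <- sum((y[-1] + y[-length(y)]) / 2 * diff(fine))
  expect_equal(band_area(f1, bd), trapz, tolerance = 1e-3)
  # no component in window
  far <- band_definition("x", 1300, c(1295, 1305), c(1288, 1388))
  expect_error(band_area(f1, far), "no fitted component")
})

test_that("relative content forms the expected ratios and rejects zero amide II", {
  rc <- relative_content(2, 1, 4)
  expect_equal(rc$collagen_ratio, 0.5)
  expect_equal(rc$pg_ratio, 0.25)
  rc2 <- relative_content(3, 3, 3)
  expect_equal(rc2$collagen_ratio, 1)
  expect_equal(rc2$pg_ratio, 1)
  expect_error(relative_content(2, 1, 0), "amide II")
})

test_that("composition ratios are grid- and scale-invariant", {
  cfg <- spectral_sim_config(noise_sd = 0, seed = 5)
  sp <- coadd(generate_depth_series(cfg)$series)
  base <- fit_composition(sp)
  # doubling the whole spectrum leaves the ratios unchanged
  sp2 <- ftir_spectrum(sp$wavenumbers, 3 * sp$absorbance)
  scaled <- fit_composition(sp2)
  expect_equal(scaled$composition$collagen_ratio,
               base$composition$collagen_ratio, tolerance = 1e-6)
  expect_equal(scaled$composition$pg_ratio, base$composition$pg_ratio,
               tolerance = 1e-6)
  # 2x finer grid changes the ratios by < 0.5%
  cfg2 <- spectral_sim_config(step = 2, noise_sd = 0, seed = 5)
  spf <- coadd(generate_depth_series(cfg2)$series)
  fine <- fit_composition(spf)
  expect_lt(abs(fine$composition$collagen_ratio /
                  base$composition$collagen_ratio - 1), 0.005)
  expect_lt(abs(fine$composition$pg_ratio / base$composition$pg_ratio - 1),
            0.005)
})
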