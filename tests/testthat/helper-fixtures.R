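# shared fixture builders (all deterministic)

# a small series y[wn, layer] from explicit layer coefficients on two bases
coef_series <- function(coefs, centers = c(1338, 1064), sigmas = c(8, 10),
                        wn = seq(1400, 1000, by = -4)) {
  mat <- sapply(seq_len(nrow(coefs)), function(j) {
    rowSums(sapply(seq_along(centers), function(b) {
      coefs[j, b] * exp(-(wn - centers[b])^2 / (2 * sigmas[b]^2))
    }))
  })
  ftir_series(wn, mat)
}

# brute-force 2D correlation maps straight from the defining double sums
brute_force_maps <- function(y) {          # y: layers m x wavenumbers n
  m <- nrow(y); n <- ncol(y)
  yt <- sweep(y, 2, colMeans(y))
  phi <- matrix(0, n, n); psi <- matrix(0, n, n)
  nm <- matrix(0, m, m)
  for (j in 1:m) for (k in 1:m) if (j != k) nm[j, k] <- 1 / (pi * (k - j))
  z <- apply(yt, 2, function(col) as.vector(nm %*% col))
  for (a in 1:n) for (b in 1:n) {
    phi[a, b] <- sum(yt[, a] * yt[, b]) / (m - 1)
    psi[a, b] <- sum(yt[, a] * z[, b]) / (m - 1)
  }
  list(phi = phi, psi = psi)
}

# straight horizontal bar polyline
bar_path <- function(row, cols) cbind(row = rep(row, length(cols)), col = cols)

# semicircular arc polyline of radius r centred at (cy, cx)
arc_path <- function(cy, cx, r, npts = 400) {
  t <- seq(0, pi, length.out = npts)
  cbind(row = cy + r * sin(t), col = cx + r * cos(t))
}
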