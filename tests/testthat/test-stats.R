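test_that("Mann-Whitney U handles separation, ties and degenerate samples", {
  sep <- mann_whitney(c(1, 1, 1, 1), c(5, 5, 5, 5, 5, 5))
  expect_equal(sep$u, 0)
  same <- mann_whitney(rep(2, 4), rep(2, 6))
  expect_equal(same$u, 12)          # n_a * n_b / 2
  expect_equal(same$z, 0)
  expect_true(same$all_tied)
  # equal mean ranks under a non-degenerate tie structure still give Z = 0
  a <- c(1, 3, 3, 5); b <- c(1, 1, 3, 3, 5, 5)
  mw <- mann_whitney(a, b)
  expect_equal(mw$mean_rank_a, mw$mean_rank_b)
  expect_equal(mw$z, 0)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("U agrees with wilcox.test and swapping groups flips Z", {
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:5, 4, replace = TRUE)
    b <- sample(1:5, 6, replace = TRUE)
    mw <- mann_whitney(a, b)
    w <- suppressWarnings(stats::wilcox.test(a, b))
    u_a <- unname(w$statistic)
    expect_equal(mw$u, min(u_a, 4 * 6 - u_a))
    rev <- mann_whitney(b, a)
    expect_equal(rev$u, mw$u)
    expect_equal(rev$z, -mw$z)
    # rank-sum conservation
    n <- 10
    expect_equal(mw$n_a * mw$mean_rank_a + mw$n_b * mw$mean_rank_b,
                 n * (n + 1) / 2)
  }
})

test_that("normal-approximation p tracks the exact enumeration for small N", {
  # with heavy ties at N = 8 the two p-values can drift apart in the
  # centre of the null distribution, but in the decision-relevant tail
  # (exact p < 0.1) the tie-corrected normal approximation stays within
  # 0.05 of the full enumeration
  set.seed(17)
  tail_cases <- 0
  for (i in 1:500) {
    a <- sample(1:4, 3, replace = TRUE)
    b <- sample(1:4, 5, replace = TRUE)
    mw <- mann_whitney(a, b, exact = "always")
    expect_false(is.na(mw$p_exact))
    if (mw$p_exact < 0.1) {
      tail_cases <- tail_cases + 1
      expect_lt(abs(mw$p - mw$p_exact), 0.05)
    }
  }
  expect_gte(tail_cases, 10)
  expect_error(mann_whitney(1:10, 1:10, exact = "always"), "N <= 12")
})

test_that("U reconstruction from mean ranks obeys the rank-sum identity", {
  # no separation: both groups at the global mean rank
  expect_equal(u_from_mean_ranks(5.5, 4, 6, 5.5), 12)
  # identity violation beyond rounding is an error
  expect_error(u_from_mean_ranks(2.0, 4, 6, 7.33), "rank-sum identity")
})

test_that("one-way ANOVA and Tukey HSD match textbook formulas", {
  # hand example: SSB = 6, SSW = 6 -> F(2, 6) = 3
  x <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey(x, g)
  expect_equal(res$f, 3)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)

  same <- anova_tukey(rep(c(1, 2), 6), rep(c("a", "b", "c"), each = 4))
  expect_equal(same$f, 0)

  degen <- anova_tukey(rep(c(0, 1), each = 3), rep(c("a", "b"), each = 3))
  expect_true(degen$degenerate)
  expect_equal(degen$f, Inf)

  # five groups with the study design sizes against a formula-level oracle
  set.seed(8)
  sizes <- c(6, 4, 6, 4, 10)
  means <- c(0, 1, 0.5, 2, 0)
  vals <- unlist(mapply(function(n, m) rnorm(n, m), sizes, means,
                        SIMPLIFY = FALSE))
  grp <- rep(paste0("g", 1:5), sizes)
  res5 <- anova_tukey(vals, grp)
  k <- 5; n <- sum(sizes)
  gm <- mean(vals)
  mg <- tapply(vals, grp, mean)
  ssb <- sum(table(grp)[names(mg)] * (mg - gm)^2)
  ssw <- sum((vals - mg[grp])^2)
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res5$f, unname(f_oracle), tolerance = 1e-8)
  expect_equal(res5$p, unname(stats::pf(f_oracle, k - 1, n - k,
                                        lower.tail = FALSE)),
               tolerance = 1e-8)
  # Tukey-Kramer adjusted p for each pair via the studentized range
  mse <- ssw / (n - k)
  counts <- table(grp)
  for (r in seq_len(nrow(res5$tukey))) {
    pr <- strsplit(res5$tukey$pair[r], "-")[[1]]
    se <- sqrt(mse / 2 * (1 / counts[pr[1]] + 1 / counts[pr[2]]))
    q <- abs(mg[pr[1]] - mg[pr[2]]) / se
    p_oracle <- stats::ptukey(q, k, n - k, lower.tail = FALSE)
    expect_equal(res5$tukey$p_adj[r], unname(p_oracle), tolerance = 1e-8)
  }
})

test_that("ANOVA F is invariant to shifts and scalings of the data", {
  set.seed(4)
  x <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  f0 <- anova_tukey(x, g)$f
  expect_equal(anova_tukey(x + 100, g)$f, f0, tolerance = 1e-10)
  expect_equal(anova_tukey(3.7 * x, g)$f, f0, tolerance = 1e-10)
})

test_that("detectable difference solves the noncentral-t power equation", {
  d <- detectable_difference(5, 8, 0.05, 0.95)
  expect_gt(d, 20.5)
  expect_lt(d, 22.5)
  # agrees with the base power solver
  expect_equal(d, stats::power.t.test(n = 5, sd = 8, sig.level = 0.05,
                                      power = 0.95)$delta,
               tolerance = 1e-6)
  # exact scale equivariance in sd
  expect_equal(detectable_difference(5, 16), 2 * detectable_difference(5, 8),
               tolerance = 1e-8)
  expect_error(detectable_difference(1, 8), "at least 2")
})

test_that("forward Monte-Carlo power matches the analytic solution", {
  n <- 5; sd <- 8; alpha <- 0.05; target <- 0.8
  d <- detectable_difference(n, sd, alpha, target)
  set.seed(99)
  rej <- replicate(4000, {
    stats::t.test(rnorm(n, 0, sd), rnorm(n, d, sd),
                  var.equal = TRUE)$p.value < alpha
  })
  expect_lt(abs(mean(rej) - target), 0.02)
})
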