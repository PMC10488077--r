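#' Mann-Whitney U comparison of two groups
#'
#' Midranks are assigned over the pooled data; each group's U is its rank
#' sum minus n(n+1)/2, and the reported U is the smaller of the two. The Z
#' statistic uses the tie-corrected normal approximation
#' SE = sqrt( (n_a n_b / 12) * ( (N + 1) - sum(t^3 - t) / (N (N - 1)) ) )
#' with t the tie-group sizes, and no continuity correction - the
#' convention under which the study's score comparisons were reported. Z is
#' signed by the first group's U, so swapping the groups flips its sign.
#' An exact permutation p-value (full enumeration over group assignments of
#' the observed midranks) is available for pooled N <= 12.
#'
#' @param scores_a,scores_b Numeric (typically ordinal) samples.
#' @param exact `"never"` (default), `"always"` (errors for N > 12) or
#'   `"auto"` (exact when N <= 12).
#' @return An object of class `group_comparison`: `u`, `z`, `p`,
#'   `p_exact` (or `NA`), `mean_rank_a`, `mean_rank_b`, `n_a`, `n_b`,
#'   `all_tied` flag.
#' @export
mann_whitney <- function(scores_a, scores_b,
                         exact = c("never", "auto", "always")) {
  exact <- match.arg(exact)
  scores_a <- as.numeric(scores_a); scores_b <- as.numeric(scores_b)
  n_a <- length(scores_a); n_b <- length(scores_b)
  if (n_a < 1 || n_b < 1) stop("both groups must be non-empty")
  pooled <- c(scores_a, scores_b)
  rk <- rank(pooled, ties.method = "average")
  n <- n_a + n_b
  r_a <- sum(rk[seq_len(n_a)])
  u_a <- r_a - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  mu <- n_a * n_b / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  se2 <- (n_a * n_b / 12) * ((n + 1) - tie_term)
  all_tied <- se2 <= 0
  z <- if (all_tied) 0 else (u_a - mu) / sqrt(se2)
  p <- if (all_tied) 1 else min(1, 2 * stats::pnorm(-abs(z)))
  p_exact <- NA_real_
  if (exact == "always" && n > 12) {
    stop("exact enumeration is limited to pooled N <= 12")
  }
  if ((exact == "always") || (exact == "auto" && n <= 12)) {
    combos <- utils::combn(n, n_a)
    u_all <- colSums(matrix(rk[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
    p_exact <- mean(abs(u_all - mu) >= abs(u_a - mu) - 1e-9)
  }
  structure(list(u = min(u_a, u_b), z = z, p = p, p_exact = p_exact,
                 mean_rank_a = r_a / n_a, mean_rank_b = sum(rk[-seq_len(n_a)]) / n_b,
                 n_a = n_a, n_b = n_b, all_tied = all_tied),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %g, Z = %.3f, p = %.4g (mean ranks %.2f vs %.2f; n = %d, %d)\n",
              x$u, x$z, x$p, x$mean_rank_a, x$mean_rank_b, x$n_a, x$n_b))
  invisible(x)
}

#' Reconstruct Mann-Whitney U from printed mean ranks
#'
#' Given a group's printed mean rank, its rank sum is `mean_rank * n`, its
#' U is the rank sum minus n(n+1)/2, and the complementary group's U is
#' n_a n_b minus that; the smaller of the two is returned (the reporting
#' convention of the study tables). The rank-sum identity
#' n_a mr_a + n_b mr_b = N(N+1)/2 is checked within a rounding tolerance
#' when both mean ranks are supplied.
#'
#' @param mean_rank_a First group's mean rank.
#' @param n_a,n_b Group sizes.
#' @param mean_rank_b Optional second mean rank, used only for the
#'   consistency check.
#' @param tol Allowed rank-sum discrepancy from printing precision
#'   (default 0.1).
#' @return The reconstructed U (numeric scalar).
#' @export
u_from_mean_ranks <- function(mean_rank_a, n_a, n_b, mean_rank_b = NULL,
                              tol = 0.1) {
  n <- n_a + n_b
  if (!is.null(mean_rank_b)) {
    total <- n_a * mean_rank_a + n_b * mean_rank_b
    if (abs(total - n * (n + 1) / 2) > tol) {
      stop(sprintf("rank-sum identity violated: %g vs %g", total,
                   n * (n + 1) / 2))
    }
  }
  u_a <- mean_rank_a * n_a - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  min(u_a, u_b)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Classical fixed-effects one-way ANOVA followed by Tukey's honestly
#' significant difference test; unequal group sizes are handled by the
#' Tukey-Kramer form of the studentized-range comparison. Zero within-group
#' variance with unequal means is flagged and reported as an infinite F.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor), >= 2 groups with >= 2
#'   observations each.
#' @return An object of class `anova_result`: `f`, `df_between`,
#'   `df_within`, `p`, `tukey` (data frame: `pair`, `diff`, `p_adj`),
#'   `group_means`, `degenerate` flag.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  k <- nlevels(groups)
  n <- length(values)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]       # row 1 = between groups, row 2 = residuals
  ssw <- tab[2, "Sum Sq"]
  means <- tapply(values, groups, mean)
  degenerate <- FALSE
  if (ssw <= .Machine$double.eps * sum(values^2) &&
      max(means) - min(means) > 0) {
    degenerate <- TRUE
    f <- Inf; p <- 0
    tukey <- data.frame(pair = character(0), diff = numeric(0),
                        p_adj = numeric(0))
  } else {
    f <- tab[1, "F value"]
    p <- tab[1, "Pr(>F)"]
    th <- stats::TukeyHSD(fit)$groups
    tukey <- data.frame(pair = rownames(th), diff = th[, "diff"],
                        p_adj = th[, "p adj"], row.names = NULL)
  }
  structure(list(f = f, df_between = k - 1, df_within = n - k, p = p,
                 tukey = tukey, group_means = means, degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

#' Smallest detectable mean difference of a two-sample t test
#'
#' Solves for the difference between means Delta at which a two-sided,
#' two-sample t test with `n_per_group` observations per group and common
#' standard deviation `sd` reaches the requested power: power(Delta) =
#' P(|T| > t_crit) with T noncentral t on 2n - 2 degrees of freedom and
#' noncentrality Delta / (sd * sqrt(2/n)). Delta scales exactly linearly
#' with `sd`.
#'
#' @param n_per_group Observations per group, >= 2.
#' @param sd Common standard deviation (same units as the means).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.95).
#' @return The detectable difference Delta (same units as `sd`).
#' @export
detectable_difference <- function(n_per_group, sd, alpha = 0.05,
                                  power = 0.95) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (sd <= 0) stop("sd must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= alpha || power >= 1) {
    stop("power must lie in (alpha, 1)")
  }
  df <- 2 * n_per_group - 2
  tc <- stats::qt(1 - alpha / 2, df)
  pw <- function(delta) {
    ncp <- delta / (sd * sqrt(2 / n_per_group))
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  hi <- sd
  while (pw(hi) < power) {
    hi <- hi * 2
    if (hi > 1e6 * sd) stop("requested power unattainable")
  }
  stats::uniroot(function(d) pw(d) - power, c(0, hi), tol = 1e-10)$root
}
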