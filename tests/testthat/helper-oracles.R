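# Independent slow oracles used to validate the fast implementations.

# Exhaustive permutation test for a difference in means: two-sided p of the
# t statistic over all label assignments of the pooled sample. Uses the
# mid-p convention (ties at the observed statistic count half), the
# appropriate summary when comparing a discrete permutation distribution
# with a continuous parametric p value.
permutation_t_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  tstat <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  idx <- utils::combn(length(pooled), n)
  obs <- abs(tstat(x, y))
  ts <- abs(apply(idx, 2, function(i) tstat(pooled[i], pooled[-i])))
  mean(ts > obs + 1e-12) + 0.5 * mean(abs(ts - obs) <= 1e-12)
}

# Two-tailed variance-ratio p by numerical quadrature of the F density.
f_p_quadrature <- function(f, df1, df2) {
  dens <- function(u) stats::df(u, df1, df2)
  lower <- stats::integrate(dens, 0, f, rel.tol = 1e-10)$value
  min(1, 2 * min(lower, 1 - lower))
}

# Textbook sums-of-squares decomposition for a balanced two-way layout.
balanced_anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y) / (nlevels(a) * nlevels(b))
  gm <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  ss_a <- n * nlevels(b) * sum((ma - gm)^2)
  ss_b <- n * nlevels(a) * sum((mb - gm)^2)
  cell_dev <- 0
  for (la in levels(a)) for (lb in levels(b)) {
    m <- mean(y[a == la & b == lb])
    cell_dev <- cell_dev + n * (m - ma[[la]] - mb[[lb]] + gm)^2
  }
  ss_e <- sum((y - mab[interaction(a, b)])^2)
  df_e <- length(y) - nlevels(a) * nlevels(b)
  list(
    f_a = (ss_a / (nlevels(a) - 1)) / (ss_e / df_e),
    f_b = (ss_b / (nlevels(b) - 1)) / (ss_e / df_e),
    f_ab = (cell_dev / ((nlevels(a) - 1) * (nlevels(b) - 1))) / (ss_e / df_e))
}
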