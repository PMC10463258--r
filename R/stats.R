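#' Hypothesis-test result container
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (one or two values).
#' @param p_value Two-tailed p value in `[0, 1]`.
#' @param test_name One of `"t_test"`, `"f_test"`, `"two_way_anova"`.
#' @param effect Optional effect label (for ANOVA terms).
#' @return An object of class `"splice_test"`.
#' @keywords internal
splice_test <- function(statistic, df, p_value, test_name, effect = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_name = test_name,
                 effect = effect),
            class = "splice_test")
}

#' @export
print.splice_test <- function(x, ...) {
  cat(x$test_name,
      if (!is.null(x$effect)) paste0("[", x$effect, "]"),
      sprintf(": statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Unpaired two-tailed t test
#'
#' Student's pooled-variance t test by default (the convention for
#' comparing splice-ratio replicates between conditions), Welch's unequal
#' variance version with `welch = TRUE`. Degenerate samples with zero
#' pooled variance are handled explicitly: equal means give `p = 1`,
#' unequal means `p = 0`.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param welch Use the Welch correction instead of pooling.
#' @return A `splice_test` with the t statistic, degrees of freedom and
#'   two-tailed p value.
#' @export
#' @examples
#' t_test_unpaired(c(1, 2, 3, 4), c(3, 4, 5, 6))
t_test_unpaired <- function(x, y, welch = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(splice_test(if (equal) 0 else Inf,
                       length(x) + length(y) - 2,
                       if (equal) 1 else 0, "t_test"))
  }
  tt <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  splice_test(tt$statistic, tt$parameter, tt$p.value, "t_test")
}

#' Two-tailed variance-ratio F test
#'
#' Compares the dispersion of two samples: `F = var(x) / var(y)` with
#' `(n_x - 1, n_y - 1)` degrees of freedom and two-tailed
#' `p = 2 min(P(F <= f), P(F >= f))` capped at 1. Used to ask whether one
#' group's expression levels span a wider range than another's (the
#' direction of the difference is not assumed, hence two tails).
#'
#' @param x,y Numeric samples, each of size >= 2; `y` must have positive
#'   variance.
#' @return A `splice_test` with the F statistic, both degrees of freedom
#'   and the two-tailed p value. Swapping `x` and `y` inverts the statistic
#'   but leaves the p value unchanged.
#' @export
#' @examples
#' f_test_variance(rnorm(20, sd = 2), rnorm(20, sd = 1))
f_test_variance <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2, length(y) >= 2)
  vy <- stats::var(y)
  if (vy == 0) stop("denominator sample has zero variance")
  f <- stats::var(x) / vy
  df <- c(length(x) - 1, length(y) - 1)
  lo <- stats::pf(f, df[1], df[2])
  p <- min(1, 2 * min(lo, 1 - lo))
  splice_test(f, df, p, "f_test")
}

#' Two-way analysis of variance
#'
#' F tests for both main effects and the interaction in a two-factor
#' layout, using Type II sums of squares so that unbalanced designs (e.g.
#' three or four experiments per group) are handled marginally:
#' `SS(A | B)`, `SS(B | A)` and `SS(AB | A, B)`, computed by comparing
#' nested least-squares fits. Degenerate zero-variance cases follow the
#' natural conventions: an effect with zero sum of squares has
#' `F = 0, p = 1` even when the residual variance is also zero; a nonzero
#' effect with zero residual variance has `F = Inf, p = 0`.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or vectors coercible to factors) of
#'   the same length as `values`, each with >= 2 levels; every
#'   combination of levels must be observed at least once.
#' @return A list of three `splice_test` objects named `factor_a`,
#'   `factor_b`, `interaction`.
#' @export
#' @examples
#' g <- expand.grid(a = c("wt", "ko"), b = c("ctrl", "bdnf"), rep = 1:3)
#' y <- rnorm(nrow(g)) + (g$a == "ko") * (g$b == "bdnf")
#' two_way_anova(y, g$a, g$b)
two_way_anova <- function(values, factor_a, factor_b) {
  stopifnot(is.numeric(values),
            length(values) == length(factor_a),
            length(values) == length(factor_b))
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("each factor needs at least two levels")
  tab <- table(a, b)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", rownames(tab)[empty[1]], " x ",
         colnames(tab)[empty[2]])
  }
  dat <- data.frame(y = values, a = a, b = b)
  rss_of <- function(form) sum(stats::residuals(stats::lm(form, dat))^2)
  rss_a <- rss_of(y ~ a)
  rss_b <- rss_of(y ~ b)
  rss_ab <- rss_of(y ~ a + b)
  rss_full <- rss_of(y ~ a * b)
  ss <- c(factor_a = rss_b - rss_ab,          # SS(A | B)
          factor_b = rss_a - rss_ab,          # SS(B | A)
          interaction = rss_ab - rss_full)    # SS(AB | A, B)
  eff_df <- c(factor_a = nlevels(a) - 1L,
              factor_b = nlevels(b) - 1L,
              interaction = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  rdf <- length(values) - nlevels(a) * nlevels(b)
  total <- sum((values - mean(values))^2)
  one <- function(label) {
    eff_ss <- max(ss[[label]], 0)
    if (eff_ss <= 1e-12 * max(total, 1)) {
      f <- 0; p <- 1
    } else if (rss_full <= 1e-12 * total || rdf == 0) {
      f <- Inf; p <- 0
    } else {
      f <- (eff_ss / eff_df[[label]]) / (rss_full / rdf)
      p <- stats::pf(f, eff_df[[label]], rdf, lower.tail = FALSE)
    }
    splice_test(f, c(eff_df[[label]], rdf), p, "two_way_anova",
                effect = label)
  }
  list(factor_a = one("factor_a"),
       factor_b = one("factor_b"),
       interaction = one("interaction"))
}
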