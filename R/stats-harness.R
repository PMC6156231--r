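# Normality-gated test selection and the comparison battery.
#
# Policy: Shapiro-Wilk on every group at the 5% rejection level. If all
# groups pass, parametric tests are used (paired t, unpaired equal-variance
# t, one-way ANOVA); if any group fails, the nonparametric counterparts
# (Wilcoxon signed-rank, Mann-Whitney U, Kruskal-Wallis). All tests
# two-sided. The named tests themselves come from base R's stats package;
# the package's contribution is the deterministic selection policy and the
# bookkeeping around it.

tg_is_normal <- function(x, alpha = 0.05) {
  if (length(unique(x)) == 1L) return(FALSE)  # degenerate: not testable
  shapiro.test(x)$p.value > alpha
}

#' Select the statistical test for a set of groups
#'
#' Deterministic test choice from pairing, group count and per-group
#' Shapiro-Wilk normality verdicts at the 5% level.
#'
#' @param groups List of numeric vectors (each group `n >= 3`).
#' @param paired Logical; paired comparisons require exactly two groups of
#'   equal length.
#' @param alpha Normality rejection level (default 0.05).
#' @return Character test name: one of `"paired t-test"`,
#'   `"Wilcoxon signed-rank"`, `"t-test"`, `"Mann-Whitney U"`,
#'   `"one-way ANOVA"`, `"Kruskal-Wallis"`.
#' @export
#' @examples
#' set.seed(1)
#' choose_test(list(rnorm(20), rnorm(20)), paired = TRUE)
choose_test <- function(groups, paired = FALSE, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  ns <- lengths(groups)
  if (any(ns < 3L))
    stop("every group needs n >= 3 (got ", paste(ns, collapse = ", "), ")")
  if (paired) {
    if (length(groups) != 2L)
      stop("paired comparisons support exactly two groups")
    if (ns[1] != ns[2])
      stop("paired groups must have equal length")
  }
  normal <- vapply(groups, tg_is_normal, logical(1), alpha = alpha)
  k <- length(groups)
  if (all(normal)) {
    if (paired) "paired t-test"
    else if (k == 2L) "t-test"
    else "one-way ANOVA"
  } else {
    if (paired) "Wilcoxon signed-rank"
    else if (k == 2L) "Mann-Whitney U"
    else "Kruskal-Wallis"
  }
}

#' Run one comparison under the test-selection policy
#'
#' Applies [choose_test()] and executes the chosen test (two-sided). The
#' unpaired t-test uses the equal-variance form by default (`var_equal =
#' FALSE` switches to Welch). Rank tests use the standard mid-rank tie
#' handling (and therefore the normal approximation when ties are
#' present).
#'
#' @inheritParams choose_test
#' @param label Free-text label carried into the result.
#' @param var_equal Equal-variance unpaired t (default `TRUE`).
#' @return An object of class `"comparison_result"`: `label`, `test`,
#'   `statistic`, `p_value`, `n` (per group), `normal` (per-group
#'   verdicts), `paired`, `direction` (sign of mean difference
#'   group1 - group2 for two groups, else `NA`).
#' @export
run_comparison <- function(groups, paired = FALSE, label = "",
                           alpha = 0.05, var_equal = TRUE) {
  test <- choose_test(groups, paired = paired, alpha = alpha)
  normal <- vapply(groups, tg_is_normal, logical(1), alpha = alpha)
  g1 <- groups[[1L]]
  g2 <- if (length(groups) >= 2L) groups[[2L]] else NULL
  res <- switch(
    test,
    "paired t-test" = t.test(g1, g2, paired = TRUE),
    "t-test" = t.test(g1, g2, var.equal = var_equal),
    "Wilcoxon signed-rank" = suppressWarnings(
      wilcox.test(g1, g2, paired = TRUE)),
    "Mann-Whitney U" = suppressWarnings(wilcox.test(g1, g2)),
    "one-way ANOVA" = {
      y <- unlist(groups)
      f <- factor(rep(seq_along(groups), lengths(groups)))
      a <- summary(aov(y ~ f))[[1]]
      list(statistic = c(F = a[1, "F value"]), p.value = a[1, "Pr(>F)"])
    },
    "Kruskal-Wallis" = kruskal.test(groups))
  direction <- if (length(groups) == 2L)
    sign(mean(g1) - mean(g2)) else NA_real_
  structure(list(label = label, test = test,
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n = lengths(groups),
                 normal = normal,
                 paired = paired,
                 direction = direction),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.3g, n = %s\n",
              if (nzchar(x$label)) x$label else "comparison",
              x$test, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Two-way ANOVA interaction test
#'
#' Tests whether a manipulation's effect depends on a second factor
#' (typically laser x stimulus size) via the interaction term of a
#' two-factor ANOVA on the supplied observations.
#'
#' With identical cell means and zero residual variance the F statistic is
#' undefined; the function returns p = 1 in that degenerate case (no
#' evidence of interaction) rather than refusing.
#'
#' @param data Data.frame of observations.
#' @param response,f1,f2 Column names of the response and the two factors.
#' @return List with `p_interaction`, `F_interaction`, `df`, and the full
#'   `anova` table.
#' @export
interaction_test <- function(data, response = "evoked_hz",
                             f1 = "laser_on", f2 = "size_deg") {
  for (cn in c(response, f1, f2))
    if (!cn %in% names(data)) stop("missing column: ", cn)
  a <- factor(data[[f1]]); b <- factor(data[[f2]])
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels")
  tabn <- table(a, b)
  if (any(tabn == 0L)) stop("empty factor cells; cannot test interaction")
  if (any(tabn < 2L)) stop("need >= 2 observations per cell")
  y <- data[[response]]
  fit <- aov(y ~ a * b)
  tab <- summary(fit)[[1]]
  row <- grep(":", rownames(tab))
  Fv <- tab[row, "F value"]
  p <- tab[row, "Pr(>F)"]
  # degenerate inputs (e.g. identical cell means with zero noise) leave
  # only floating-point dust in the sums of squares; report p = 1
  scale <- sum(y^2) + 1
  res_ss <- tab[nrow(tab), "Sum Sq"]
  if (!is.finite(p) ||
      (res_ss < 1e-12 * scale && tab[row, "Sum Sq"] < 1e-12 * scale)) {
    p <- 1
    Fv <- NA_real_
  }
  list(p_interaction = p, F_interaction = Fv,
       df = unname(tab[row, "Df"]), anova = tab)
}

#' Bonferroni-corrected decisions
#'
#' @param p Vector of p-values.
#' @param m Number of comparisons in the family (defaults to
#'   `length(p)`; must be at least that).
#' @param alpha Family-wise level (default 0.05).
#' @return Data.frame with `p`, `p_adjusted` (`min(1, p * m)`), and
#'   `reject` (`p <= alpha / m`).
#' @export
#' @examples
#' bonferroni(c(0.02, 0.01), m = 3)
bonferroni <- function(p, m = length(p), alpha = 0.05) {
  stopifnot(m >= length(p), all(p >= 0 & p <= 1))
  data.frame(p = p,
             p_adjusted = pmin(1, p * m),
             reject = p <= alpha / m)
}
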