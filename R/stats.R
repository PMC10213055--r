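#' @include conditions.R
NULL

# Uniform lightweight container for the cohort statistical layer. The
# workhorse computations are the standard stats-package implementations;
# this layer adds the contracts (typed errors on degenerate input) and a
# stable result shape.
.tilTest <- function(method, statistic, p.value, n, ...) {
  structure(list(method = method, statistic = unname(statistic),
                 p.value = unname(p.value), n = n, ...),
            class = "til_test")
}

#' @export
print.til_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p.value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two unpaired samples. The p-value is exact
#' whenever feasible (no ties, combined n < 50) and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @return a `til_test` with the U statistic (of `x` relative to `y`).
#' @export
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y))
    tilValidationStop("both samples must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  .tilTest("Mann-Whitney", ht$statistic, ht$p.value,
           n = c(length(x), length(y)))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided comparison, e.g. pre- vs post-treatment densities of
#' self-matched specimens. Zero differences are dropped (the standard
#' convention); an all-zero difference vector is an error, not a p-value.
#' For up to 15 nonzero differences the two-sided p-value is exact, by full
#' enumeration of the 2^n sign assignments on the midranks of the absolute
#' differences (so ties are handled exactly too); larger samples use the
#' standard exact/normal-approximation machinery of [stats::wilcox.test()].
#'
#' @param pre,post paired numeric vectors of equal length.
#' @return a `til_test` with the signed-rank statistic V (of `post`
#'   relative to `pre`).
#' @export
wilcoxonSignedRank <- function(pre, post) {
  if (length(pre) != length(post))
    tilContractStop("pre and post must have equal length")
  d <- post - pre
  if (!length(d) || all(d == 0))
    tilValidationStop("all paired differences are zero")
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v0 <- sum(rk[d > 0])
  if (n <= 15L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% rk)
    p <- min(1, 2 * min(mean(vs <= v0), mean(vs >= v0)))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE,
                         alternative = "two.sided"))$p.value
  }
  .tilTest("Wilcoxon signed-rank", v0, p, n = n)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of two or more groups, with tie correction;
#' p-value from the chi-square distribution on k - 1 df.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return a `til_test` with the H statistic.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    tilValidationStop("at least two groups are required")
  if (any(!lengths(groups)))
    tilValidationStop("every group must be non-empty")
  ht <- stats::kruskal.test(groups)
  .tilTest("Kruskal-Wallis", ht$statistic, ht$p.value, n = lengths(groups))
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction by default (set `correct = TRUE` for the
#' Yates-corrected 2x2 version). All margins must be positive.
#'
#' @param table matrix of non-negative integer counts.
#' @param correct apply continuity correction (2x2 only).
#' @return a `til_test` with the chi-square statistic and its df.
#' @export
#' @examples
#' chiSquareTest(matrix(c(24, 6, 12, 23), 2))  # response-by-arm table
chiSquareTest <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
    tilValidationStop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    tilValidationStop("all table margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  .tilTest("Pearson chi-square", ht$statistic, ht$p.value,
           n = sum(table), df = unname(ht$parameter))
}

#' Spearman rank correlation
#'
#' rho computed as the Pearson correlation of midranks; exact p-value for
#' small tie-free samples, t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return a `til_test` with `estimate` carrying rho.
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    tilValidationStop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    tilValidationStop("correlation undefined for a constant vector")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  .tilTest("Spearman rank correlation", ht$statistic, ht$p.value,
           n = length(x), estimate = unname(ht$estimate))
}

#' Two-way ANOVA with pairwise multiple comparisons
#'
#' Least-squares fit of `values ~ A * B` on a (possibly unbalanced)
#' two-factor design — in the cohort analyses A is pathological response
#' (non-MPR/MPR) and B is timepoint (pre/post). Main effects are tested
#' with Type II sums of squares (each main effect adjusted for the other,
#' via model comparison), the interaction from the full model. All pairwise
#' cell-mean contrasts are tested with t statistics on the pooled residual
#' variance and Holm-adjusted. Degenerate zero-variance fits are resolved
#' deterministically: a zero sum of squares over a zero residual variance
#' gives F = 0 (p = 1), a positive one gives an infinite F (p = 0).
#'
#' @param values numeric response.
#' @param factorA,factorB factors (or coercible) of the same length.
#' @return list with `anova` (term, df, F, p) and `pairwise` (cell pairs,
#'   estimate, t, p, p_adj).
#' @export
twoWayAnova <- function(values, factorA, factorB) {
  A <- factor(factorA); B <- factor(factorB)
  if (length(values) != length(A) || length(values) != length(B))
    tilContractStop("values and factors must have equal length")
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    tilValidationStop("both factors need at least two levels")
  tab <- table(A, B)
  if (any(tab == 0))
    tilValidationStop("every cell of the design must have n >= 1")
  dat <- data.frame(y = values, A = A, B = B)
  fit <- stats::lm(y ~ A * B, data = dat)
  rssOf <- function(form) sum(stats::lm(form, data = dat)$residuals^2)
  rssFull <- sum(stats::resid(fit)^2)
  ss <- c(A = rssOf(y ~ B) - rssOf(y ~ A + B),
          B = rssOf(y ~ A) - rssOf(y ~ A + B),
          `A:B` = rssOf(y ~ A + B) - rssFull)
  ss <- pmax(ss, 0)
  dfs <- c(nlevels(A) - 1, nlevels(B) - 1,
           (nlevels(A) - 1) * (nlevels(B) - 1))
  dfe <- fit$df.residual
  if (dfe < 1L)
    tilValidationStop("no residual degrees of freedom (saturated design)")
  mse <- rssFull / dfe
  eps <- 1e-12 * (sum(values^2) + 1)
  fstat <- if (mse > eps) (ss / dfs) / mse else ifelse(ss <= eps, 0, Inf)
  anova_tab <- data.frame(term = names(ss), df = dfs,
                          statistic = unname(fstat),
                          p.value = stats::pf(unname(fstat), dfs, dfe,
                                              lower.tail = FALSE),
                          row.names = NULL)
  # pairwise cell contrasts on the cell-means parameterisation
  cell <- interaction(A, B, sep = ":")
  mse <- sum(stats::resid(fit)^2) / fit$df.residual
  means <- tapply(values, cell, mean)
  ns <- tapply(values, cell, length)
  cmb <- utils::combn(names(means), 2)
  est <- means[cmb[1, ]] - means[cmb[2, ]]
  se <- sqrt(mse * (1 / ns[cmb[1, ]] + 1 / ns[cmb[2, ]]))
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                         estimate = unname(est), t = unname(tstat),
                         p.value = unname(p),
                         p_adj = stats::p.adjust(p, "holm"),
                         row.names = NULL)
  list(anova = anova_tab, pairwise = pairwise)
}
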