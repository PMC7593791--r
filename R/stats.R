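# Covariate-adjusted group statistics: ANCOVA-style partial F-tests,
# adjusted pairwise t-tests, Bonferroni correction, chi-square tests of
# independence and partial correlations.  All p-values are two-sided.

stat_result <- function(statistic_name, value, df, p_raw, n,
                        covariates = character(), p_adjusted = NULL) {
  structure(list(statistic_name = statistic_name, value = value, df = df,
                 p_raw = p_raw, p_adjusted = p_adjusted,
                 covariates = covariates, n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$statistic_name, " = ", signif(x$value, 5),
      " (df ", paste(x$df, collapse = ", "), "), p = ", signif(x$p_raw, 4),
      if (!is.null(x$p_adjusted)) paste0(", p_adj = ", signif(x$p_adjusted, 4)),
      if (length(x$covariates)) paste0(" | covariates: ",
                                       paste(x$covariates, collapse = "+")),
      "\n", sep = "")
  invisible(x)
}

# design-matrix helper shared by the linear-model tests; errors on rank
# deficiency naming the offending columns
build_design <- function(n, covariates) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(intercept)")))
  X <- as.matrix(covariates)
  if (nrow(X) != n) stopf("covariate rows (%d) != observations (%d)", nrow(X), n)
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  cbind("(intercept)" = 1, X)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

rss_of <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Covariate-adjusted group comparison (ANCOVA partial F-test)
#'
#' Fits the linear model `y ~ intercept + group + covariates` by exact
#' least squares and tests the group indicators with a partial F-test
#' against the covariate-only model.  With no covariates this is exactly
#' one-way ANOVA.
#'
#' @param y Per-subject response values.
#' @param group Group labels (character or factor), at least 2 groups with
#'   2+ subjects each.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (e.g. age and 0/1 sex), same row order as `y`.
#' @return A `stat_result` with `statistic_name = "F"` and `df = c(df1, df2)`.
#' @export
ancova_group_test <- function(y, group, covariates = NULL) {
  y <- as.numeric(y)
  group <- factor(group)
  keep <- stats::complete.cases(y, group,
                                if (is.null(covariates)) rep(TRUE, length(y)) else covariates)
  if (!all(keep)) {
    clubnet_log(sprintf("ancova: dropping %d subject(s) with missing data",
                        sum(!keep)))
    y <- y[keep]; group <- droplevels(group[keep])
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  tab <- table(group)
  if (length(tab) < 2 || any(tab < 2)) {
    stopf("need >= 2 groups with >= 2 subjects each (got %s)",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  n <- length(y)
  X0 <- build_design(n, covariates)
  Gm <- stats::model.matrix(~group)[, -1, drop = FALSE]
  X1 <- cbind(X0, Gm)
  check_full_rank(X1)
  rss0 <- rss_of(y, X0)
  rss1 <- rss_of(y, X1)
  df1 <- ncol(Gm)
  df2 <- n - ncol(X1)
  # covariates alone already fit y perfectly: the group adds nothing
  tol <- 1e-12 * max(sum((y - mean(y))^2), .Machine$double.eps)
  if (rss0 <= tol) {
    Fv <- 0
    p <- 1
  } else {
    Fv <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  stat_result("F", Fv, c(df1, df2), p, n,
              covariates = colnames(X0)[-1])
}

#' Covariate-adjusted two-group t-test
#'
#' The t-statistic of the group indicator in
#' `y ~ intercept + indicator + covariates`; with no covariates this
#' equals the classic equal-variance two-sample t-test.  Its square equals
#' the two-group ANCOVA F with the same covariates.
#'
#' @inheritParams ancova_group_test
#' @param group Labels with exactly 2 distinct values after subsetting.
#' @return A `stat_result` with `statistic_name = "t"`.
#' @export
adjusted_pairwise_t <- function(y, group, covariates = NULL) {
  y <- as.numeric(y)
  group <- factor(group)
  keep <- stats::complete.cases(y, group,
                                if (is.null(covariates)) rep(TRUE, length(y)) else covariates)
  y <- y[keep]; group <- droplevels(group[keep])
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  if (nlevels(group) != 2) stopf("pairwise t-test needs exactly 2 groups, got %d",
                                 nlevels(group))
  if (any(table(group) < 1)) stopf("both groups must be non-empty")
  n <- length(y)
  X0 <- build_design(n, covariates)
  ind <- as.numeric(group == levels(group)[2])
  X <- cbind(X0, indicator = ind)
  check_full_rank(X)
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
  tv <- fit$coefficients["indicator"] / se
  p <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  stat_result("t", unname(tv), df, unname(p), n, covariates = colnames(X0)[-1])
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * m)` for a declared family size `m` (which may
#' exceed the number of p-values supplied, e.g. when some contrasts were
#' not computed).
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size, `>= length(p_values)`; defaults to the number of
#'   p-values.
#' @return Adjusted p-values, same order.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stopf("family size m = %d smaller than the %d p-values supplied",
          m, length(p_values))
  }
  pmin(1, p_values * m)
}

#' Pearson chi-square test of independence
#'
#' Classic chi-square on an r x k contingency table (no continuity
#' correction), e.g. sex by diagnostic group.
#'
#' @param counts Matrix of nonnegative integer counts with no zero row or
#'   column margin.
#' @return A `stat_result` with `statistic_name = "chi2"` and
#'   `df = (r-1)(k-1)`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stopf("contingency table has a zero margin")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  stat_result("chi2", chi2, df, p, sum(counts))
}

#' Partial correlation
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on
#' an intercept plus the covariates; the p-value comes from
#' `t = r * sqrt((n - 2 - c) / (1 - r^2))` with `c` covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariate matrix/data.frame (age, sex, ...).
#' @return A `stat_result` with `statistic_name = "r"`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- stats::complete.cases(x, y,
                                if (is.null(covariates)) rep(TRUE, length(x)) else covariates)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    clubnet_log(sprintf("partial correlation: excluding %d subject(s) with missing scores",
                        n_dropped))
  }
  x <- x[keep]; y <- y[keep]
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(x)
  cc <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= cc + 2) stopf("need n > covariates + 2 (n = %d, covariates = %d)", n, cc)
  X <- build_design(n, covariates)
  check_full_rank(X)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    stopf("degenerate residuals: zero variance after removing covariates")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - cc
  tv <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  stat_result("r", r, df, p, n,
              covariates = if (cc) colnames(X)[-1] else character())
}
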