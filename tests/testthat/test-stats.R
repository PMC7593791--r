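# Independent oracle: ordinary-least-squares via explicit normal equations.
ols_rss <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

test_that("ancova F matches the normal-equations oracle on a small dataset", {
  set.seed(10)
  n <- 9
  group <- rep(c("HC", "SCD", "aMCI"), each = 3)
  age <- rnorm(n, 70, 5)
  y <- rnorm(n) + (group == "aMCI") * 1.5 + 0.05 * age

  res <- ancova_group_test(y, group, cbind(age = age))

  X0 <- cbind(1, age)
  G <- model.matrix(~factor(group))[, -1]
  X1 <- cbind(X0, G)
  rss0 <- ols_rss(y, X0); rss1 <- ols_rss(y, X1)
  Fo <- ((rss0 - rss1) / 2) / (rss1 / (n - 4))
  expect_equal(res$value, Fo, tolerance = 1e-9)
  expect_equal(res$df, c(2, 5))
  expect_equal(res$p_raw, pf(Fo, 2, 5, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("ancova with no covariates equals classic one-way ANOVA", {
  set.seed(11)
  for (i in 1:5) {
    y <- rnorm(30)
    g <- sample(c("HC", "SCD", "aMCI"), 30, replace = TRUE,
                prob = c(.4, .3, .3))
    if (min(table(g)) < 2 || length(unique(g)) < 3) next
    res <- ancova_group_test(y, g)
    ref <- anova(lm(y ~ factor(g)))
    expect_equal(res$value, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(res$p_raw, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
})

test_that("a covariate identical to y absorbs all group variance", {
  set.seed(12)
  y <- rnorm(24)
  g <- rep(c("HC", "aMCI"), each = 12)
  res <- ancova_group_test(y, g, cbind(z = y))
  expect_lt(res$value, 1e-18)
  expect_gt(res$p_raw, 0.999)
})

test_that("ancova validates groups and rank", {
  expect_error(ancova_group_test(1:4, c("HC", "HC", "HC", "SCD")), ">= 2")
  y <- rnorm(12)
  g <- rep(c("a", "b"), 6)
  x <- rnorm(12)
  expect_error(ancova_group_test(y, g, cbind(x = x, x2 = 2 * x)),
               "rank deficient.*x2")
})

test_that("adjusted pairwise t equals the closed-form two-sample t", {
  set.seed(13)
  y1 <- rnorm(20, 0, 0.1); y2 <- rnorm(20, 1, 0.1)
  y <- c(y1, y2); g <- rep(c("HC", "aMCI"), each = 20)
  res <- adjusted_pairwise_t(y, g)
  ref <- t.test(y1, y2, var.equal = TRUE)
  expect_equal(abs(res$value), abs(unname(ref$statistic)), tolerance = 1e-9)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-9)
  expect_equal(res$df, 38)
})

test_that("t squared equals the two-group ancova F with identical covariates", {
  set.seed(14)
  for (i in 1:5) {
    n <- 30
    y <- rnorm(n); g <- rep(c("x", "y"), each = 15)
    covs <- cbind(age = rnorm(n, 70, 5), sex = rbinom(n, 1, .5))
    tt <- adjusted_pairwise_t(y, g, covs)
    ff <- ancova_group_test(y, g, covs)
    expect_equal(tt$value^2, ff$value, tolerance = 1e-9)
  }
})

test_that("a shift fully explained by age is not significant after adjustment", {
  set.seed(15)
  rejections <- 0
  for (i in 1:50) {
    age <- c(rnorm(20, 65, 3), rnorm(20, 75, 3))
    y <- 0.1 * age + rnorm(40, 0, 0.05)
    g <- rep(c("young", "old"), each = 20)
    t_adj <- adjusted_pairwise_t(y, g, cbind(age = age))
    rejections <- rejections + (t_adj$p_raw < 0.05)
  }
  expect_lte(rejections / 50, 0.2)
})

test_that("bonferroni caps at 1 and respects the declared family", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(c(0.2, 0.4)), c(0.4, 0.8))
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
})

test_that("chi-square matches hand computation", {
  r0 <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$value, 0)
  expect_equal(r0$p_raw, 1)

  r1 <- chi_square_independence(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r1$value, 40)
  expect_equal(r1$df, 1)

  r2 <- chi_square_independence(matrix(c(5, 6, 7, 8, 9, 10), 2))
  expect_equal(r2$df, 2)
  # agreement with stats::chisq.test (no continuity correction)
  ref <- suppressWarnings(chisq.test(matrix(c(5, 6, 7, 8, 9, 10), 2),
                                     correct = FALSE))
  expect_equal(r2$value, unname(ref$statistic), tolerance = 1e-12)

  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("partial correlation matches the first-order recursive formula", {
  set.seed(16)
  n <- 8
  z <- rnorm(n)
  x <- 0.8 * z + rnorm(n)
  y <- -0.5 * z + rnorm(n)
  res <- partial_correlation(x, y, cbind(z = z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$value, oracle, tolerance = 1e-9)
  expect_equal(res$df, n - 3)

  # y = x with an uninformative covariate: r = 1
  x2 <- rnorm(20)
  expect_equal(partial_correlation(x2, x2, cbind(z = rnorm(20)))$value, 1.0)

  # both exact functions of the covariate: degenerate
  age <- rnorm(20, 70, 5)
  expect_error(partial_correlation(2 * age, -age, cbind(age = age)),
               "degenerate")
})

test_that("missing scores are excluded pairwise with the rest retained", {
  set.seed(17)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.1)
  y[c(3, 7)] <- NA
  res <- partial_correlation(x, y, cbind(z = rnorm(30)))
  expect_equal(res$n, 28)
  expect_gt(res$value, 0.9)
})
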