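test_that("symmetric duplicated groups give zero contrast and p near 1", {
  set.seed(61)
  base <- data.frame(y = rnorm(12), age = rnorm(12, 15), sex = rep(c("F", "M"), 6))
  df <- rbind(cbind(base, group = "A"), cbind(base, group = "B"))
  fit <- adjusted_linear_comparison(df$y, df$group, df$age, df$sex)
  expect_equal(fit$contrasts$estimate, 0, tolerance = 1e-10)
  expect_equal(fit$contrasts$p, 1, tolerance = 1e-10)
})

test_that("a planted group effect is recovered with tiny noise", {
  set.seed(62)
  n <- 20
  grp <- rep(c("A", "B"), each = n)
  age <- rnorm(2 * n, 15)
  sex <- sample(c("F", "M"), 2 * n, TRUE)
  y <- ifelse(grp == "B", 2, 0) + rnorm(2 * n, 0, 1e-6)
  fit <- adjusted_linear_comparison(y, grp, age, sex)
  expect_equal(abs(fit$contrasts$estimate), 2, tolerance = 1e-4)
  expect_lt(fit$contrasts$p, 1e-12)
})

test_that("coefficients and marginal means equal the normal-equation solution", {
  # six points, two groups, one covariate pattern; solved directly via
  # beta = (X'X)^-1 X'y
  y <- c(1, 2, 3, 5, 6, 7)
  grp <- rep(c("A", "B"), each = 3)
  age <- c(10, 12, 14, 10, 12, 14)
  sex <- c(0, 1, 0, 0, 1, 0)
  X <- cbind(1, c(0, 0, 0, 1, 1, 1), age, sex)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- adjusted_linear_comparison(y, grp, age, sex)
  expect_equal(unname(fit$coef), unname(drop(beta)), tolerance = 1e-10)
  emm_A <- beta[1] + beta[3] * mean(age) + beta[4] * mean(sex)
  expect_equal(fit$emmeans$emmean[1], unname(emm_A), tolerance = 1e-10)
  expect_equal(fit$contrasts$estimate, unname(-beta[2]), tolerance = 1e-10)
})

test_that("marginal means and contrasts agree with emmeans", {
  set.seed(63)
  df <- data.frame(y = rnorm(60),
                   group = sample(c("HC", "PC", "MI"), 60, TRUE),
                   age = rnorm(60, 15, 2),
                   sex = sample(c("F", "M"), 60, TRUE))
  while (any(table(df$group) < 3)) df$group <- sample(df$group)
  fit <- adjusted_linear_comparison(df$y, df$group, df$age, df$sex)
  lmfit <- lm(y ~ group + age + sex01,
              data = transform(df, sex01 = as.numeric(factor(sex)) - 1))
  # reduce every covariate to its pooled mean, the convention used here
  em <- emmeans::emmeans(lmfit, "group", cov.keep = character(0))
  em_df <- as.data.frame(em)
  expect_equal(fit$emmeans$emmean, em_df$emmean, tolerance = 1e-8)
  expect_equal(fit$emmeans$se, em_df$SE, tolerance = 1e-8)
  expect_equal(fit$emmeans$lower, em_df$lower.CL, tolerance = 1e-8)
  ct <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  expect_equal(sort(abs(fit$contrasts$estimate)), sort(abs(ct$estimate)),
               tolerance = 1e-8)
  expect_equal(sort(fit$contrasts$p), sort(ct$p.value), tolerance = 1e-8)
})

test_that("with group-balanced covariates contrasts reduce to mean differences", {
  set.seed(64)
  covpat <- data.frame(age = rnorm(10, 15), sex = rep(c("F", "M"), 5))
  df <- rbind(cbind(covpat, group = "A", y = rnorm(10, 0)),
              cbind(covpat, group = "B", y = rnorm(10, 1)),
              cbind(covpat, group = "C", y = rnorm(10, 2)))
  fit <- adjusted_linear_comparison(df$y, df$group, df$age, df$sex)
  means <- tapply(df$y, df$group, mean)
  expect_equal(fit$contrasts$estimate[fit$contrasts$contrast == "A - B"],
               unname(means["A"] - means["B"]), tolerance = 1e-10)
  expect_equal(fit$emmeans$emmean, as.numeric(means), tolerance = 1e-10)
})

test_that("design validation: group sizes and rank deficiency", {
  expect_error(adjusted_linear_comparison(rnorm(5), c("A", "A", "A", "B", "B"),
                                          rnorm(5), rep(0, 5)), "n >= 3")
  set.seed(65)
  expect_error(adjusted_linear_comparison(rnorm(10), rep(c("A", "B"), 5),
                                          rep(2, 10), rep(0, 10)),
               "rank deficient")
})

test_that("Mann-Whitney U counts exceedances and handles identical samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  mw2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw2$U, 9)
  same <- mann_whitney(1:9, 1:9)
  expect_gt(same$p, 0.95)
  # exact mode agrees with the exact distribution for small untied samples
  ex <- mann_whitney(c(1.1, 2.3), c(3.7, 4.2, 5.9), exact = TRUE)
  expect_equal(ex$p, 2 * (1 / choose(5, 2)))
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("chi-square without continuity correction matches hand values", {
  expect_equal(chi_square(matrix(10, 2, 2))$statistic, 0)
  # 2x2 (20,10;10,20): chi2 = 60*(20*20-10*10)^2/(30*30*30*30) = 6.6667
  cs <- chi_square(matrix(c(20, 10, 10, 20), 2))
  expect_equal(cs$statistic, 60 * (400 - 100)^2 / 30^4, tolerance = 1e-12)
  expect_equal(cs$df, 1)
  expect_error(chi_square(matrix(c(-1, 2, 3, 4), 2)), ">= 0")
})

test_that("BH adjustment matches brute-force step-up enumeration", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.2), q = 0.05)
  expect_equal(sum(res$rejected), 4L)
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  all1 <- bh_fdr(rep(1, 6))
  expect_false(any(all1$rejected))
  expect_equal(all1$adjusted, rep(1, 6))

  set.seed(66)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    mine <- bh_fdr(p, q)
    ref <- brute_force_bh(p, q)
    expect_equal(mine$adjusted, ref$adjusted, tolerance = 1e-12)
    expect_identical(mine$rejected, ref$rejected)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("comparison tables keep FDR-p above raw p and honor family policy", {
  set.seed(67)
  df <- data.frame(group = rep(c("HC", "PC", "MVS", "MI"), c(15, 14, 14, 12)),
                   age = rnorm(55, 15), sex = sample(c("F", "M"), 55, TRUE))
  for (m in paste0("m", 1:4)) df[[m]] <- rnorm(55)
  tab <- compare_metrics(df, paste0("m", 1:4))
  expect_s3_class(tab, "comparison_table")
  expect_equal(nrow(tab$contrasts), 4 * 6)
  expect_true(all(tab$contrasts$fdr_p >= tab$contrasts$p - 1e-12))
  ord <- order(tab$contrasts$p)
  expect_true(all(diff(tab$contrasts$fdr_p[ord]) >= -1e-12))
  # CI contains the marginal mean
  expect_true(all(tab$emmeans$lower <= tab$emmeans$emmean &
                    tab$emmeans$emmean <= tab$emmeans$upper))
  # per-metric family adjusts within metric only
  pm <- compare_metrics(df, paste0("m", 1:4), family = "per-metric")
  m1 <- pm$contrasts$metric == "m1"
  expect_equal(pm$contrasts$fdr_p[m1],
               p.adjust(pm$contrasts$p[m1], "BH"), tolerance = 1e-12)
})
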