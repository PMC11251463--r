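#' Age- and sex-adjusted linear model with pairwise group contrasts
#'
#' Ordinary least squares of a metric on group indicators plus age and sex,
#' with estimated marginal means (model-predicted group means with age and
#' sex held at the pooled sample means) and all pairwise group contrasts
#' with t-based two-sided p-values and 95% confidence intervals. Sex is
#' coded as a binary indicator. Covariate terms cancel in the contrasts, so
#' each contrast equals the difference of group coefficients.
#'
#' @param y numeric metric values.
#' @param group factor (or coercible) of group membership; >= 2 levels,
#'   each with n >= 3.
#' @param age numeric covariate.
#' @param sex factor/character with two levels, or 0/1 numeric.
#' @param conf_level confidence level for marginal-mean and contrast CIs.
#' @return Object of class `adjusted_comparison`: `emmeans` (`data.frame`
#'   of group, emmean, se, lower, upper), `contrasts` (`data.frame` of
#'   contrast, estimate, se, df, t, p, lower, upper), `df_residual`.
#' @export
adjusted_linear_comparison <- function(y, group, age, sex,
                                       conf_level = 0.95) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (any(table(group) < 3L)) stop("each group needs n >= 3")
  sex01 <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  keep <- complete.cases(y, group, age, sex01)
  y <- y[keep]; group <- droplevels(group[keep])
  age <- age[keep]; sex01 <- sex01[keep]
  X <- model.matrix(~ group + age + sex01)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  n <- length(y)
  beta <- qr.coef(qrX, y)
  resid <- y - X %*% beta
  df_res <- n - ncol(X)
  sigma2 <- sum(resid^2) / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  V <- sigma2 * XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))

  lv <- levels(group)
  # row of the design matrix for group g at pooled covariate means
  emm_row <- function(g) {
    x <- setNames(numeric(ncol(X)), colnames(X))
    x["(Intercept)"] <- 1
    gcol <- paste0("group", g)
    if (gcol %in% names(x)) x[gcol] <- 1
    x["age"] <- mean(age)
    x["sex01"] <- mean(sex01)
    x
  }
  tq <- qt(1 - (1 - conf_level) / 2, df_res)
  emms <- do.call(rbind, lapply(lv, function(g) {
    x <- emm_row(g)
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    data.frame(group = g, emmean = est, se = se,
               lower = est - tq * se, upper = est + tq * se,
               stringsAsFactors = FALSE)
  }))
  prs <- utils::combn(lv, 2L)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    g1 <- prs[1L, i]; g2 <- prs[2L, i]
    cvec <- emm_row(g1) - emm_row(g2)
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    data.frame(contrast = paste(g1, "-", g2), estimate = est, se = se,
               df = df_res, t = tval, p = 2 * pt(-abs(tval), df_res),
               lower = est - tq * se, upper = est + tq * se,
               stringsAsFactors = FALSE)
  }))
  structure(list(emmeans = emms, contrasts = contrasts,
                 df_residual = df_res, coef = beta, vcov = V),
            class = "adjusted_comparison")
}

#' @export
print.adjusted_comparison <- function(x, ...) {
  cat("adjusted_comparison (age- and sex-adjusted linear model)\n")
  print(x$emmeans, row.names = FALSE, digits = 4)
  print(x$contrasts[, c("contrast", "estimate", "p")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test; U counts, over all pairs, how often a value of `x`
#' exceeds a value of `y` (ties counted 1/2). The p-value uses the
#' tie-corrected normal approximation by default; `exact = TRUE` requests
#' exact enumeration (appropriate for small untied samples).
#'
#' @param x,y numeric samples.
#' @param exact logical (default `FALSE`).
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction.
#'
#' @param tab matrix or table of counts (>= 0).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be >= 0")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR procedure: adjusted `p_i = min_{j >= i} (m * p_(j) / j)`
#' capped at 1; hypotheses with adjusted p <= `q` form the rejection set
#' (equivalent to the classical step-up rule at level q).
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (same order as input), `rejected`
#'   (logical), `q`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.2))$rejected
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adjusted <- p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, rejected = !is.na(adjusted) & adjusted <= q,
       q = q)
}

#' FDR-corrected adjusted comparisons over a family of metrics
#'
#' Runs [adjusted_linear_comparison()] for each metric column and applies
#' [bh_fdr()] across all resulting contrasts as one family (the per-table
#' reading of correcting "for the overall number of tests"; with
#' `family = "per-metric"` each metric is corrected separately).
#'
#' @param data `data.frame` with one row per subject.
#' @param metrics character vector of metric column names.
#' @param group_col,age_col,sex_col column names (defaults `"group"`,
#'   `"age"`, `"sex"`).
#' @param q FDR level.
#' @param family `"per-table"` (default) or `"per-metric"`.
#' @return Object of class `comparison_table`: `contrasts` (`data.frame`
#'   with metric, contrast, estimate, se, df, t, raw p, fdr p), `emmeans`
#'   (metric x group marginal means with CIs), `q`, `family`.
#' @export
compare_metrics <- function(data, metrics, group_col = "group",
                            age_col = "age", sex_col = "sex",
                            q = 0.05, family = c("per-table", "per-metric")) {
  family <- match.arg(family)
  fits <- lapply(metrics, function(m)
    adjusted_linear_comparison(data[[m]], data[[group_col]],
                               data[[age_col]], data[[sex_col]]))
  names(fits) <- metrics
  contrasts <- do.call(rbind, lapply(metrics, function(m)
    cbind(metric = m, fits[[m]]$contrasts, stringsAsFactors = FALSE)))
  emms <- do.call(rbind, lapply(metrics, function(m)
    cbind(metric = m, fits[[m]]$emmeans, stringsAsFactors = FALSE)))
  if (family == "per-table") {
    contrasts$fdr_p <- bh_fdr(contrasts$p, q)$adjusted
  } else {
    contrasts$fdr_p <- NA_real_
    for (m in metrics) {
      sel <- contrasts$metric == m
      contrasts$fdr_p[sel] <- bh_fdr(contrasts$p[sel], q)$adjusted
    }
  }
  rownames(contrasts) <- rownames(emms) <- NULL
  structure(list(contrasts = contrasts, emmeans = emms, q = q,
                 family = family, test = "age- and sex-adjusted linear model"),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("comparison_table (", x$test, "; FDR q = ", x$q, ", family = ",
      x$family, ")\n", sep = "")
  print(x$contrasts[, c("metric", "contrast", "estimate", "p", "fdr_p")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
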