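#' Frequentist replication suite
#'
#' Classical counterparts of the Bayesian analyses: Pearson chi-squared on
#' 2x2 demographic tables, two-sample t-tests, tie-safe Spearman correlation,
#' two-step hierarchical regression with an R-squared-change F-test, median
#' split of the metabolite, and one-way ANOVA with Tukey HSD comparisons.
#' All fits go through base R (`chisq.test`, `t.test`, `lm`, `aov`).
#'
#' @name frequentist
NULL

test_result <- function(statistic, df, p_value, estimate = NA_real_, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), estimate = unname(estimate),
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df_txt <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$method, x$statistic, df_txt, x$p_value))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction, df = 1 — the convention that reproduces the
#' demographic gender comparison of small CHR/HC cohorts.
#'
#' @param table 2x2 matrix of nonnegative integer counts with all margins
#'   positive.
#' @return A `test_result` with method `"pearson_chi2"`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 count table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: expected counts undefined")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result(ct$statistic, ct$parameter, ct$p.value, method = "pearson_chi2")
}

#' Two-sample t-test
#'
#' @param a,b numeric vectors, each with at least 2 non-missing values.
#' @param pooled if `TRUE` (default) the pooled-variance (Student) test;
#'   otherwise Welch.
#' @return A `test_result` (method `"t_pooled"` or `"t_welch"`) whose
#'   `estimate` is the mean difference `mean(a) - mean(b)`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  if (stats::var(a) + stats::var(b) == 0)
    stop("zero combined variance: t statistic undefined")
  tt <- stats::t.test(a, b, var.equal = pooled)
  test_result(tt$statistic, tt$parameter, tt$p.value,
              estimate = mean(a) - mean(b),
              method = if (pooled) "t_pooled" else "t_welch")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks (safe under ties), with the two-sided
#' p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped and at
#'   least 3 complete pairs are required.
#' @return A `test_result` (method `"spearman"`) whose `estimate` is rho.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant vector: correlation undefined")
  rho <- stats::cor(midranks(x), midranks(y))
  if (abs(rho) >= 1) {
    p <- 0
    stat <- sign(rho) * Inf
  } else {
    stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(stat), df = n - 2)
  }
  test_result(stat, n - 2, p, estimate = rho, method = "spearman")
}

#' Two-step hierarchical regression with R-squared-change F-test
#'
#' Ordinary least squares of `y` on the step-1 predictors, then on step 1
#' plus step 2; the increment is tested with the F-change statistic on
#' `(k_added, n - k_total - 1)` degrees of freedom.
#'
#' @param y numeric response.
#' @param step1_predictors,step2_predictors numeric matrices (or vectors)
#'   of predictors entered at each step.
#' @return A list of class `hier_reg_result` with elements `step1`
#'   (`r2`, `adj_r2`, `f`, `df`, `p`), `step2` (`r2`, `delta_r2`,
#'   `f_change`, `df`, `p`) and `coefficients` (a tibble of per-term `B`,
#'   `t`, `p` for the full model).
#' @export
hierarchical_regression <- function(y, step1_predictors, step2_predictors) {
  x1 <- as.matrix(step1_predictors)
  x2 <- as.matrix(step2_predictors)
  n <- length(y)
  if (nrow(x1) != n || nrow(x2) != n) stop("predictor rows must match length(y)")
  k1 <- ncol(x1); k2 <- ncol(x2)
  if (n <= k1 + k2 + 1L) stop("too few observations for the full model")
  if (is.null(colnames(x1))) colnames(x1) <- paste0("step1_", seq_len(k1))
  if (is.null(colnames(x2))) colnames(x2) <- paste0("step2_", seq_len(k2))
  d1 <- data.frame(y = y, x1)
  d2 <- data.frame(y = y, x1, x2)
  fit1 <- stats::lm(y ~ ., data = d1)
  fit2 <- stats::lm(y ~ ., data = d2)
  if (fit1$rank < k1 + 1L || fit2$rank < k1 + k2 + 1L)
    stop("rank-deficient design matrix")
  s1 <- summary(fit1); s2 <- summary(fit2)
  cmp <- stats::anova(fit1, fit2)
  co <- stats::coef(s2)
  structure(
    list(
      step1 = list(r2 = s1$r.squared, adj_r2 = s1$adj.r.squared,
                   f = unname(s1$fstatistic[1L]),
                   df = unname(s1$fstatistic[2:3]),
                   p = stats::pf(s1$fstatistic[1L], s1$fstatistic[2L],
                                 s1$fstatistic[3L], lower.tail = FALSE)),
      step2 = list(r2 = s2$r.squared,
                   delta_r2 = s2$r.squared - s1$r.squared,
                   f_change = cmp$F[2L],
                   df = c(cmp$Df[2L], cmp$Res.Df[2L]),
                   p = cmp$`Pr(>F)`[2L]),
      coefficients = tibble::tibble(
        term = rownames(co),
        B = co[, "Estimate"],
        t = co[, "t value"],
        p = co[, "Pr(>|t|)"]
      )
    ),
    class = "hier_reg_result"
  )
}

#' Median split into low/high subgroups
#'
#' Values strictly above the sample median are labelled `"high"`; values at
#' or below it `"low"`, so 13 distinct values split 7 low / 6 high.
#'
#' @param values numeric vector of length at least 2.
#' @return Character vector of `"low"`/`"high"` labels.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to split")
  med <- stats::median(values, na.rm = TRUE)
  ifelse(values > med, "high", "low")
}

#' One-way ANOVA with Tukey HSD comparisons
#'
#' @param values numeric response.
#' @param labels group label vector (k >= 2 groups, each with >= 2 values).
#' @return A list with `omnibus` (a `test_result`, method `"anova"`) and
#'   `tukey` (a tibble of pairwise differences with Tukey-adjusted p-values
#'   from the studentized-range distribution).
#' @export
anova_tukey <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(as.character(labels)[ok])
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  if (any(table(labels) < 2L)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ labels)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$labels
  structure(
    list(
      omnibus = test_result(an[1L, "F value"],
                            c(an[1L, "Df"], an[2L, "Df"]),
                            an[1L, "Pr(>F)"], method = "anova"),
      tukey = tibble::tibble(
        pair = rownames(tk),
        diff = tk[, "diff"],
        lwr = tk[, "lwr"],
        upr = tk[, "upr"],
        p_adj = tk[, "p adj"]
      )
    ),
    class = "anova_tukey_result"
  )
}
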