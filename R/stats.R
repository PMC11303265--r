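#' Normality-gated two-group comparison
#'
#' Continuous variables: Shapiro-Wilk on each group at alpha = 0.05; if
#' both pass, a pooled-variance unpaired t-test, otherwise a Mann-Whitney
#' U test. A zero-variance group falls back to Mann-Whitney with a
#' warning. Categorical variables: Pearson chi-squared on the contingency
#' table without continuity correction.
#'
#' @param x,y observations per group (continuous kind), or `x` a 2-column
#'   contingency matrix (categorical kind, `y` ignored).
#' @param kind `"continuous"` or `"categorical"`.
#' @param variable optional variable name carried into the result.
#' @param alpha normality-gate level (default 0.05).
#' @return An object of class `group_comparison`: `variable`, `test`
#'   (`"t"`, `"mann_whitney"` or `"chi2"`), `statistic`, `p`, and group
#'   `summaries` (mean +- SD for normal data, median (IQR) otherwise,
#'   counts for categorical).
#' @export
compare_groups <- function(x, y = NULL, kind = c("continuous", "categorical"),
                           variable = NULL, alpha = 0.05) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    tab <- as.matrix(x)
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(structure(list(variable = variable, test = "chi2",
                          statistic = unname(ct$statistic), p = ct$p.value,
                          summaries = tab), class = "group_comparison"))
  }
  if (length(x) < 3L || length(y) < 3L)
    stop("need >= 3 observations per group")
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  normal <- if (degenerate) FALSE else
    stats::shapiro.test(x)$p.value > alpha &&
    stats::shapiro.test(y)$p.value > alpha
  if (degenerate)
    warning("zero-variance group: falling back to Mann-Whitney")
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    summ <- list(group1 = c(mean = mean(x), sd = stats::sd(x), n = length(x)),
                 group2 = c(mean = mean(y), sd = stats::sd(y), n = length(y)))
    structure(list(variable = variable, test = "t",
                   statistic = unname(tt$statistic), p = tt$p.value,
                   summaries = summ), class = "group_comparison")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    summ <- list(group1 = c(median = stats::median(x),
                            iqr = stats::IQR(x), n = length(x)),
                 group2 = c(median = stats::median(y),
                            iqr = stats::IQR(y), n = length(y)))
    structure(list(variable = variable, test = "mann_whitney",
                   statistic = unname(wt$statistic), p = wt$p.value,
                   summaries = summ), class = "group_comparison")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s = %.4f, p = %.4g\n",
              if (is.null(x$variable)) "comparison" else x$variable,
              switch(x$test, t = "t", mann_whitney = "U", chi2 = "chi2"),
              x$statistic, x$p))
  invisible(x)
}

#' Pooled-variance t-test from printed summary statistics
#'
#' Unpaired two-sample t computed from group means, SDs and sizes alone
#' (the form needed to recompute published table statistics).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mixed-design two-way ANOVA (Group x Microstate Class)
#'
#' Classical univariate mixed ANOVA with one between-subjects factor
#' (group, possibly unbalanced) and one complete within-subjects factor
#' (class): sequential sums of squares, Group tested against
#' subjects-within-groups, Class and the Group x Class interaction
#' against the class-by-subject residual. Sphericity is assessed by
#' Mauchly's test on the pooled within-group covariance; when it rejects
#' at `sphericity_alpha`, Greenhouse-Geisser-corrected p values replace
#' the uncorrected ones for the within-subject effects (both are
#' reported). Subjects with any missing class value are dropped.
#'
#' Optional Bonferroni post hoc: per-class pooled-variance t between
#' groups, adjusted by the number of classes.
#'
#' @param values numeric matrix, subjects x classes (complete rows used).
#' @param groups factor/vector of group membership, length = subjects.
#' @param posthoc run the per-class post hoc tests (default TRUE).
#' @param sphericity_alpha level for the Mauchly gate (default 0.05).
#' @return An object of class `anova_result` with a `table` (term, F,
#'   df1, df2, p, p_gg), `epsilon`, `mauchly` and optional `posthoc`
#'   data.frame.
#' @export
rm_anova_group_class <- function(values, groups, posthoc = TRUE,
                                 sphericity_alpha = 0.05) {
  values <- as.matrix(values)
  groups <- factor(groups)
  keep <- stats::complete.cases(values)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) dropped for missing class values")
    values <- values[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  n <- nrow(values); k <- ncol(values); g <- nlevels(groups)
  if (g < 2L) stop("need at least two groups")
  if (n < g + 1L) stop("too few subjects")

  gm <- mean(values)
  subj_means <- rowMeans(values)
  grp_means <- tapply(subj_means, groups, mean)
  ng <- tabulate(groups)

  ss_group <- k * sum(ng * (grp_means - gm)^2)
  ss_bs <- k * sum((subj_means - gm)^2)
  ss_subj <- ss_bs - ss_group

  dev <- values - subj_means                       # within-subject deviations
  class_eff <- colMeans(dev)                       # M_c - GM (weighted)
  ss_class <- n * sum(class_eff^2)
  cell_dev <- apply(dev, 2L, function(col) tapply(col, groups, mean))
  ss_class_int <- sum(ng * rowSums(cell_dev^2))
  ss_int <- ss_class_int - ss_class
  ss_err2 <- sum(dev^2) - ss_class_int

  df_group <- g - 1; df_subj <- n - g
  df_class <- k - 1; df_int <- (g - 1) * (k - 1); df_err2 <- (n - g) * (k - 1)

  f_group <- (ss_group / df_group) / (ss_subj / df_subj)
  f_class <- (ss_class / df_class) / (ss_err2 / df_err2)
  f_int <- (ss_int / df_int) / (ss_err2 / df_err2)

  # pooled within-group covariance of the class columns
  s_pool <- Reduce(`+`, lapply(levels(groups), function(l) {
    v <- values[groups == l, , drop = FALSE]
    (nrow(v) - 1) * stats::cov(v)
  })) / (n - g)
  eps <- .gg_epsilon(s_pool)
  mauchly <- .mauchly_test(s_pool, n_error = n - g)
  use_gg <- is.finite(mauchly$p) && mauchly$p < sphericity_alpha

  p_of <- function(f, d1, d2) stats::pf(f, d1, d2, lower.tail = FALSE)
  tab <- data.frame(
    term = c("group", "class", "group:class"),
    F = c(f_group, f_class, f_int),
    df1 = c(df_group, df_class, df_int),
    df2 = c(df_subj, df_err2, df_err2),
    p = c(p_of(f_group, df_group, df_subj),
          p_of(f_class, df_class, df_err2),
          p_of(f_int, df_int, df_err2)),
    p_gg = c(NA,
             p_of(f_class, df_class * eps, df_err2 * eps),
             p_of(f_int, df_int * eps, df_err2 * eps))
  )
  tab$p_reported <- ifelse(c(FALSE, use_gg, use_gg), tab$p_gg, tab$p)

  ph <- NULL
  if (posthoc) {
    lv <- levels(groups)
    raw <- vapply(seq_len(k), function(cl) {
      a <- values[groups == lv[1L], cl]; b <- values[groups == lv[2L], cl]
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }, numeric(1))
    ph <- bonferroni_posthoc(raw, m = k)
    ph <- cbind(class = LETTERS[seq_len(k)], ph)
  }

  structure(list(table = tab, epsilon = eps, mauchly = mauchly,
                 sphericity_corrected = use_gg, posthoc = ph,
                 ss = c(group = ss_group, subj = ss_subj, class = ss_class,
                        interaction = ss_int, error = ss_err2)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Greenhouse-Geisser epsilon = %.4f (Mauchly p = %.4g%s)\n",
              x$epsilon, x$mauchly$p,
              if (x$sphericity_corrected) ", correction applied" else ""))
  if (!is.null(x$posthoc)) {
    cat("Bonferroni post hoc:\n"); print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

.gg_epsilon <- function(s) {
  k <- ncol(s)
  d <- sweep(sweep(s, 1L, rowMeans(s)), 2L, colMeans(s)) + mean(s)
  sum(diag(d))^2 / ((k - 1) * sum(d^2))
}

.mauchly_test <- function(s, n_error) {
  k <- ncol(s)
  if (k < 3L) return(list(W = 1, statistic = 0, df = 0, p = 1))
  # orthonormal contrasts
  cm <- stats::contr.helmert(k)
  cm <- sweep(cm, 2L, sqrt(colSums(cm^2)), "/")
  tmat <- t(cm) %*% s %*% cm
  ev <- eigen(tmat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(list(W = 0, statistic = Inf,
                                df = k * (k - 1) / 2 - 1, p = 0))
  p <- k - 1
  W <- prod(ev) / (mean(ev))^p
  f <- 1 - (2 * p^2 + p + 2) / (6 * p * n_error)
  stat <- -f * n_error * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Bonferroni adjustment with the reporting cap
#'
#' Adjusted p = min(1, raw x m); adjusted values at or above 0.9999 are
#' displayed as `"> 0.9999"` (the convention of capped post hoc tables).
#' The adjustment is monotone and never decreases a p value.
#'
#' @param p_raw numeric raw p values.
#' @param m number of comparisons (default `length(p_raw)`).
#' @return data.frame with `p_raw`, `p_adj` (numeric) and `display`
#'   (character).
#' @export
bonferroni_posthoc <- function(p_raw, m = length(p_raw)) {
  if (m < 1L) stop("m must be >= 1")
  p_adj <- pmin(1, p_raw * m)
  display <- ifelse(p_adj >= 0.9999, "> 0.9999",
                    formatC(p_adj, format = "fg", digits = 4))
  data.frame(p_raw = p_raw, p_adj = p_adj, display = display,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p value uses the
#' asymptotic t approximation.
#'
#' @param x,y paired observations (>= 4 pairs).
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need >= 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
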