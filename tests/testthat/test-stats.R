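test_that("the chi-squared path reproduces a hand-checkable table", {
  tab <- matrix(c(23, 22, 9, 7), 2,
                dimnames = list(c("MD", "HC"), c("F", "M")))
  res <- compare_groups(tab, kind = "categorical", variable = "sex")
  expect_identical(res$test, "chi2")
  # independent oracle: sum (O - E)^2 / E without continuity correction
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1 under the normal gate", {
  set.seed(20)
  x <- rnorm(15)
  res <- compare_groups(x, x)
  expect_identical(res$test, "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("the normality gate routes skewed data to Mann-Whitney", {
  set.seed(22)
  x <- rexp(25)^2; y <- rexp(25)^2 + 0.5
  res <- compare_groups(x, y)
  expect_identical(res$test, "mann_whitney")
  expect_true("median" %in% names(res$summaries$group1))
  # zero-variance group falls back with a warning
  expect_warning(res0 <- compare_groups(rep(1, 10), rnorm(10)),
                 "zero-variance")
  expect_identical(res0$test, "mann_whitney")
  expect_error(compare_groups(1:2, 1:5), ">= 3")
})

test_that("summary-statistic t reproduces printed group comparisons", {
  age <- t_from_summary(56.69, 14.52, 29, 54.75, 11.93, 32)
  expect_equal(age$t, 0.5723, tolerance = 1e-4)
  expect_equal(age$df, 59)
  # symmetric in group order up to sign
  age_rev <- t_from_summary(54.75, 11.93, 32, 56.69, 14.52, 29)
  expect_equal(age_rev$t, -age$t)
  expect_equal(age_rev$p, age$p)
})

test_that("the mixed ANOVA matches the sums-of-squares oracle and aov", {
  set.seed(23)
  values <- matrix(rnorm(20 * 4, mean = rep(c(1, 2, 1.5, 3), each = 20)),
                   20, 4)
  values[11:20, 3] <- values[11:20, 3] + 1.2   # interaction signal
  groups <- rep(c("g1", "g2"), each = 10)
  res <- rm_anova_group_class(values, groups, posthoc = FALSE)
  oracle <- oracle_mixed_anova(values, groups)
  expect_equal(res$table$F[1], oracle$F_group, tolerance = 1e-9)
  expect_equal(res$table$F[2], oracle$F_class, tolerance = 1e-9)
  expect_equal(res$table$F[3], oracle$F_int, tolerance = 1e-9)

  # independent route: base aov with an Error stratum
  df <- data.frame(y = as.vector(values),
                   class = factor(rep(1:4, each = 20)),
                   group = factor(rep(groups, 4)),
                   subject = factor(rep(1:20, 4)))
  fit <- summary(stats::aov(y ~ group * class + Error(subject / class),
                            data = df))
  f_aov <- c(fit[["Error: subject"]][[1]]["group", "F value"],
             fit[["Error: subject:class"]][[1]][c("class", "group:class"),
                                                "F value"])
  expect_equal(res$table$F, unname(f_aov), tolerance = 1e-9)
})

test_that("the mixed ANOVA is invariant to location shifts", {
  set.seed(24)
  values <- matrix(rnorm(16 * 4), 16, 4)
  groups <- rep(c("a", "b"), each = 8)
  f0 <- rm_anova_group_class(values, groups, posthoc = FALSE)$table$F
  f1 <- rm_anova_group_class(values + 117.3, groups,
                             posthoc = FALSE)$table$F
  expect_equal(f0, f1, tolerance = 1e-9)
})

test_that("unbalanced designs and missing rows are handled", {
  set.seed(25)
  values <- matrix(rnorm(15 * 4), 15, 4)
  values[3, 2] <- NA
  groups <- rep(c("a", "b"), c(8, 7))
  expect_message(res <- rm_anova_group_class(values, groups,
                                             posthoc = FALSE),
                 "dropped")
  expect_equal(res$table$df2[1], 12)   # 14 subjects - 2 groups
  expect_true(all(res$table$F >= 0))
})

test_that("Bonferroni adjustment is monotone with the display cap", {
  adj <- bonferroni_posthoc(c(0.001, 0.5, 0.000025), m = 4)
  expect_equal(adj$p_adj, c(0.004, 1, 0.0001))
  expect_identical(adj$display[2], "> 0.9999")
  expect_identical(adj$display[3], "0.0001")
  set.seed(26)
  p <- sort(runif(20))
  a <- bonferroni_posthoc(p, m = 6)$p_adj
  expect_true(all(diff(a) >= 0))       # monotone
  expect_true(all(a >= p))             # never decreases
})

test_that("Spearman correlation handles monotone and degenerate inputs", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -exp(x))$rho, -1)
  expect_error(spearman_cor(rep(1, 10), 1:10), "constant")
  expect_error(spearman_cor(1:3, 3:1), ">= 4")
})
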