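test_that("classification metrics follow their definitions", {
  m <- classification_metrics(tp = 3, fn = 1, tn = 2, fp = 0)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 100)
  expect_equal(m$balanced_accuracy, 87.5)
  perfect <- classification_metrics(10, 0, 12, 0)
  expect_equal(unlist(perfect[1:4]), c(accuracy = 100, sensitivity = 100,
                                       specificity = 100,
                                       balanced_accuracy = 100))
  expect_equal(classification_metrics(25, 4, 29, 3)$balanced_accuracy,
               (25 / 29 + 29 / 32) / 2 * 100, tolerance = 1e-9)
  expect_error(classification_metrics(0, 0, 5, 1), "zero members")
})

test_that("nested LOOCV runs one outer fold per subject and separates a clean margin", {
  tb <- fix_separable_table(n_per = 8, gap = 8)
  rep <- nested_loocv_svm(tb, c_grid = c(0.01, 1, 100), seed = 1)
  expect_length(rep$predictions, 16L)
  expect_equal(rep$metrics$accuracy, 100)
  expect_equal(rep$metrics$balanced_accuracy, 100)
  # deterministic given the seed
  rep2 <- nested_loocv_svm(tb, c_grid = c(0.01, 1, 100), seed = 1)
  expect_identical(rep$predictions, rep2$predictions)
  expect_identical(rep$costs, rep2$costs)
})

test_that("no information leaks from the held-out subject into its fold", {
  tb <- fix_cohort_table(n_md = 10, n_hc = 10, seed = 3)
  base <- nested_loocv_svm(tb, c_grid = c(0.01, 1), seed = 2)
  corrupted <- tb
  i <- 7L
  corrupted$x[i, ] <- corrupted$x[i, ] * 50 + 1000
  mod <- nested_loocv_svm(corrupted, c_grid = c(0.01, 1), seed = 2)
  # fold i's trained model (cost, feature set) is untouched by the
  # corruption of its own held-out row
  expect_identical(base$costs[i], mod$costs[i])
  expect_identical(base$selected_features[[i]], mod$selected_features[[i]])
})

test_that("backward selection keeps necessary features and collapses copies", {
  # identical copies of a cleanly separable feature collapse to one
  set.seed(27)
  f <- c(rnorm(10, 0), rnorm(10, 8))
  copies <- cbind(f, f, f, f)
  y <- factor(rep(c("HC", "MD"), each = 10), levels = c("HC", "MD"))
  sel <- sequential_backward_selection(copies, y, c_grid = c(1), seed = 1)
  expect_length(sel, 1L)

  # a two-feature separable set where both are necessary: the classes
  # differ only along x1 - x2, and each marginal overlaps heavily
  set.seed(28)
  n <- 12
  x1 <- rnorm(2 * n, 0, 1)
  offset <- rep(c(0, 1), each = n)
  x2 <- x1 - offset + rnorm(2 * n, 0, 0.1)
  both <- cbind(a = x1, b = x2)
  yy <- factor(rep(c("HC", "MD"), each = n), levels = c("HC", "MD"))
  sel2 <- sequential_backward_selection(both, yy, c_grid = c(1, 10),
                                        seed = 2)
  expect_length(sel2, 2L)
})

test_that("backward selection retains the informative feature under noise", {
  keep <- 0L
  n_rep <- 30L
  for (s in seq_len(n_rep)) {
    set.seed(400 + s)
    n <- 20
    x <- cbind(sig = c(rnorm(n, 0), rnorm(n, 3)),
               matrix(rnorm(2 * n * 9), 2 * n, 9))
    colnames(x) <- c("sig", paste0("noise", 1:9))
    y <- factor(rep(c("HC", "MD"), each = n), levels = c("HC", "MD"))
    sel <- sequential_backward_selection(x, y, c_grid = c(0.1, 1),
                                         inner_k = 5, seed = s)
    if (1L %in% sel) keep <- keep + 1L
  }
  expect_gte(keep / n_rep, 0.9)
})

test_that("the permutation p value is never zero and calibrates sensibly", {
  tb <- fix_separable_table(n_per = 10, gap = 8)
  pt <- permutation_test(tb, n_perm = 100, seed = 4, mode = "fast",
                         c_grid = c(0.01, 1, 100))
  expect_gte(pt$p, 1 / 101)
  expect_equal(pt$observed, 100)
  # uninformative features: observed score near chance, p well off the floor
  set.seed(29)
  noise_tb <- feature_table(matrix(rnorm(24 * 4), 24, 4),
                            rep(c("HC", "MD"), each = 12))
  pt0 <- permutation_test(noise_tb, n_perm = 100, seed = 5, mode = "fast",
                          c_grid = c(0.01, 1))
  expect_gt(pt0$p, 0.05)
  expect_error(permutation_test(tb, n_perm = 50), "100")
})

test_that("full-mode permutation reruns the nested pipeline and stays valid", {
  tb <- fix_separable_table(n_per = 6, p_noise = 1, gap = 8)
  pt <- permutation_test(tb, n_perm = 100, seed = 6, mode = "full",
                         c_grid = c(1))
  expect_identical(pt$mode, "full")
  expect_gte(pt$p, 1 / 101)
  expect_lte(pt$p, 1)
  expect_length(pt$perm_scores, 100L)
})
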