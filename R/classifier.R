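#' Assemble a classifier feature table
#'
#' Binds the per-subject microstate feature rows with demographics into
#' the matrix the SVM consumes, with the diagnosis as a binary factor
#' (positive class `MD` by default, so "sensitivity" means patient
#' detection; switchable).
#'
#' @param features numeric matrix or data.frame, subjects x features.
#' @param labels group labels coercible to a 2-level factor.
#' @param subject_ids optional ids (default row numbers).
#' @param positive which level is the positive class (default `"MD"`).
#' @return list with `x` (matrix), `y` (factor, negative level first),
#'   `subject_ids`, `positive`.
#' @export
feature_table <- function(features, labels, subject_ids = NULL,
                          positive = "MD") {
  x <- as.matrix(features)
  if (anyNA(x)) stop("feature table contains missing values")
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two levels")
  if (!positive %in% levels(y)) stop("positive class not found in labels")
  y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(x))
  list(x = x, y = y, subject_ids = subject_ids, positive = positive)
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity (true-positive rate over the positive class),
#' specificity (true-negative rate), and balanced accuracy (their mean),
#' all in percent.
#'
#' @param tp,fn,tn,fp confusion counts (nonnegative, total > 0).
#' @return named list of percentages plus the confusion counts.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total <= 0) stop("empty confusion matrix")
  if (tp + fn == 0 || tn + fp == 0)
    stop("a class has zero members: sensitivity/specificity undefined")
  sens <- tp / (tp + fn) * 100
  spec <- tn / (tn + fp) * 100
  list(accuracy = (tp + tn) / total * 100,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

# deterministic stratified fold assignment (uses the current RNG stream)
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.zscore_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

.zscore_apply <- function(x, z) sweep(sweep(x, 2L, z$mu), 2L, z$sd, "/")

.fit_linear_svm <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
}

# Fit at the best non-degenerate cost: candidates are ranked by inner-CV
# balanced accuracy (ties to the smaller cost); a candidate whose fitted
# model predicts a single class on its own training data is a degenerate
# (anti-)majority voter and is skipped unless nothing else remains.
# Returns the fit together with the chosen cost.
.fit_best_cost <- function(x, y, c_grid, accs) {
  ord <- order(-accs, c_grid)
  fallback <- NULL
  for (j in ord) {
    fit <- .fit_linear_svm(x, y, c_grid[j])
    if (is.null(fallback)) fallback <- list(fit = fit, cost = c_grid[j])
    if (length(unique(stats::predict(fit, x))) > 1L)
      return(list(fit = fit, cost = c_grid[j]))
  }
  fallback
}

.svm_weight_vector <- function(model, p) {
  w <- as.numeric(t(model$coefs) %*% model$SV)
  if (length(w) != p) w <- rep(NA_real_, p)
  w
}

# inner-CV balanced accuracy of one cost value given a fold assignment;
# confusion pooled across folds so sparse validation folds are fine
.cv_balanced_accuracy <- function(x, y, cost, folds) {
  pos <- levels(y)[2L]; neg <- levels(y)[1L]
  tp <- fn <- tn <- fp <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    z <- .zscore_fit(x[tr, , drop = FALSE])
    fit <- .fit_linear_svm(.zscore_apply(x[tr, , drop = FALSE], z), y[tr],
                           cost)
    pred <- stats::predict(fit, .zscore_apply(x[!tr, , drop = FALSE], z))
    truth <- y[!tr]
    tp <- tp + sum(pred == pos & truth == pos)
    fn <- fn + sum(pred == neg & truth == pos)
    tn <- tn + sum(pred == neg & truth == neg)
    fp <- fp + sum(pred == pos & truth == neg)
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA
  mean(c(sens, spec), na.rm = TRUE) * 100
}

# grid search for the cost parameter; ties go to the smallest C
.grid_search_c <- function(x, y, c_grid, folds) {
  accs <- vapply(c_grid, function(cc)
    .cv_balanced_accuracy(x, y, cc, folds), numeric(1))
  list(cost = c_grid[which.max(accs)], accuracy = max(accs), all = accs)
}

#' Sequential backward feature selection
#'
#' Starts from all features and repeatedly removes the one whose removal
#' maximizes inner-CV balanced accuracy (cost re-tuned over `c_grid` for
#' every candidate subset on the same folds). A removal is accepted when
#' the best candidate is at least as good as the current subset -- so
#' redundant copies collapse -- and selection stops when every removal
#' strictly hurts, or one feature remains. Exact ties between candidate
#' removals are broken by removing the feature with the smaller absolute
#' SVM weight in the current model. All evaluation stays inside the data
#' given, so calling this on a training fold leaks nothing from held-out
#' subjects.
#'
#' @param x feature matrix.
#' @param y 2-level factor.
#' @param c_grid cost grid.
#' @param inner_k inner folds (default 5).
#' @param seed optional seed for the fold shuffle.
#' @return integer indices of the selected features (columns of `x`).
#' @export
sequential_backward_selection <- function(x, y, c_grid = c(0.01, 1, 100),
                                          inner_k = 5L, seed = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two features")
  if (!is.null(seed)) set.seed(seed)
  folds <- .stratified_folds(y, inner_k)
  current <- seq_len(ncol(x))
  gs <- .grid_search_c(x[, current, drop = FALSE], y, c_grid, folds)
  current_acc <- gs$accuracy
  while (length(current) > 1L) {
    cand_acc <- vapply(seq_along(current), function(j) {
      sub <- current[-j]
      .grid_search_c(x[, sub, drop = FALSE], y, c_grid, folds)$accuracy
    }, numeric(1))
    best <- max(cand_acc)
    if (best < current_acc - 1e-12) break
    tied <- which(cand_acc > best - 1e-12)
    if (length(tied) > 1L) {
      # remove the lowest-|weight| feature among the tied candidates
      z <- .zscore_fit(x[, current, drop = FALSE])
      fit <- .fit_linear_svm(
        .zscore_apply(x[, current, drop = FALSE], z), y, gs$cost)
      w <- abs(.svm_weight_vector(fit, length(current)))
      drop_j <- tied[which.min(w[tied])]
    } else drop_j <- tied
    current <- current[-drop_j]
    current_acc <- best
    gs <- .grid_search_c(x[, current, drop = FALSE], y, c_grid, folds)
  }
  current
}

#' Nested leave-one-out cross-validated linear SVM
#'
#' Outer loop: each subject held out once. Inner loop: stratified
#' fivefold grid search over `c_grid` selecting the cost by balanced
#' accuracy; standardization parameters and (optionally) backward
#' feature selection are fitted on the inner-training data only, so no
#' information from the held-out subject reaches the model. Outer
#' predictions are pooled into one confusion matrix.
#'
#' A cost whose fitted model predicts a single class on its own
#' training data -- a degenerate majority voter, which interacts
#' pathologically with leave-one-out validation -- is skipped in favour
#' of the next-best cost unless no alternative exists.
#'
#' @param table a [feature_table].
#' @param c_grid cost grid (default `c(0.001, 0.01, 0.1, 1, 10, 100)`).
#' @param select run backward selection inside every outer fold
#'   (default FALSE; markedly slower).
#' @param inner_k inner folds (default 5).
#' @param seed integer seed driving every fold shuffle (default 1).
#' @return An object of class `classifier_report`: per-fold predictions,
#'   chosen costs, selected features, pooled confusion and metrics,
#'   mean absolute feature weights.
#' @export
nested_loocv_svm <- function(table, c_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                             select = FALSE, inner_k = 5L, seed = 1L) {
  x <- table$x; y <- table$y
  n <- nrow(x); p <- ncol(x)
  if (n < 10L) stop("need at least 10 subjects")
  if (nlevels(y) != 2L || any(tabulate(y) < 2L))
    stop("both classes must be present")
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  costs <- numeric(n)
  selected <- vector("list", n)
  wsum <- numeric(p); wn <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    xt <- x[tr, , drop = FALSE]; yt <- y[tr]
    set.seed(seed + i)               # per-fold deterministic shuffle
    feats <- seq_len(p)
    if (select)
      feats <- sequential_backward_selection(xt, yt, c_grid, inner_k)
    folds <- .stratified_folds(yt, inner_k)
    accs <- vapply(c_grid, function(cc)
      .cv_balanced_accuracy(xt[, feats, drop = FALSE], yt, cc, folds),
      numeric(1))
    z <- .zscore_fit(xt[, feats, drop = FALSE])
    best <- .fit_best_cost(.zscore_apply(xt[, feats, drop = FALSE], z),
                           yt, c_grid, accs)
    fit <- best$fit
    pred[i] <- stats::predict(
      fit, .zscore_apply(x[i, feats, drop = FALSE], z))
    costs[i] <- best$cost
    selected[[i]] <- feats
    w <- .svm_weight_vector(fit, length(feats))
    if (!anyNA(w)) { wsum[feats] <- wsum[feats] + abs(w); wn <- wn + 1L }
  }
  pos <- levels(y)[2L]; neg <- levels(y)[1L]
  tp <- sum(pred == pos & y == pos); fn <- sum(pred == neg & y == pos)
  tn <- sum(pred == neg & y == neg); fp <- sum(pred == pos & y == neg)
  metrics <- classification_metrics(tp, fn, tn, fp)
  feat_names <- colnames(x)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(p))
  structure(list(
    predictions = pred, truth = y, costs = costs,
    selected_features = selected, metrics = metrics,
    mean_abs_weight = stats::setNames(
      if (wn > 0) wsum / wn else rep(NA_real_, p), feat_names),
    n = n, positive = pos, seed = seed
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<classifier_report: n = %d, accuracy %.2f%%, ",
                     "sensitivity %.2f%%, specificity %.2f%%, ",
                     "balanced %.2f%%>\n"),
              x$n, m$accuracy, m$sensitivity, m$specificity,
              m$balanced_accuracy))
  invisible(x)
}

#' Label-permutation significance test
#'
#' Permutes the diagnosis labels and re-scores the classifier, giving
#' `p = (b + 1) / (n_perm + 1)` where `b` counts permutations whose
#' balanced accuracy reaches the observed one; by construction p is
#' never exactly 0 and its floor is `1/(n_perm + 1)`.
#'
#' Two budgets: `"full"` re-runs the whole nested pipeline per
#' permutation (exchangeable with the observed score, expensive);
#' `"fast"` freezes the feature set and the modal cost from the observed
#' run and scores plain LOOCV per permutation -- anti-conservative with
#' respect to the selection step, and labelled as such.
#'
#' @param table a [feature_table].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param mode `"fast"` or `"full"`.
#' @param c_grid cost grid.
#' @param select passed to the observed/nested runs.
#' @param report optional precomputed observed [nested_loocv_svm] report.
#' @return list with `p`, `observed` (balanced accuracy %), `perm_scores`,
#'   `mode`.
#' @export
permutation_test <- function(table, n_perm = 999L, seed = 1L,
                             mode = c("fast", "full"),
                             c_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                             select = FALSE, report = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (is.null(report))
    report <- nested_loocv_svm(table, c_grid, select = select, seed = seed)
  observed <- report$metrics$balanced_accuracy
  y <- table$y; n <- length(y)
  cost_fix <- as.numeric(names(sort(table(report$costs),
                                    decreasing = TRUE))[1L])
  set.seed(seed)
  scores <- vapply(seq_len(n_perm), function(b) {
    yp <- y[sample.int(n)]
    tb <- list(x = table$x, y = yp, subject_ids = table$subject_ids,
               positive = table$positive)
    if (mode == "full") {
      nested_loocv_svm(tb, c_grid, select = select,
                       seed = seed + b)$metrics$balanced_accuracy
    } else {
      .loocv_fixed_balacc(table$x, yp, cost_fix)
    }
  }, numeric(1))
  b <- sum(scores >= observed - 1e-12)
  list(p = (b + 1) / (n_perm + 1), observed = observed,
       perm_scores = scores, mode = mode, cost_fixed = cost_fix)
}

# plain LOOCV balanced accuracy at a fixed cost (permutation fast mode)
.loocv_fixed_balacc <- function(x, y, cost) {
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    z <- .zscore_fit(x[tr, , drop = FALSE])
    fit <- .fit_linear_svm(.zscore_apply(x[tr, , drop = FALSE], z), y[tr],
                           cost)
    pred[i] <- stats::predict(fit, .zscore_apply(x[i, , drop = FALSE], z))
  }
  pos <- levels(y)[2L]; neg <- levels(y)[1L]
  sens <- sum(pred == pos & y == pos) / sum(y == pos)
  spec <- sum(pred == neg & y == neg) / sum(y == neg)
  (sens + spec) / 2 * 100
}
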