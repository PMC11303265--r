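test_that("AAHC recovers a clean two-class partition exactly", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  truth_maps <- tset$maps[, 1:2]
  maps <- fix_noisy_copies(truth_maps, per = 3, snr = 10, seed = 2)
  res <- aahc_cluster(maps, 2)
  got <- attr(res, "assignment")
  expect_identical(got[1:3], rep(got[1], 3))
  expect_identical(got[4:6], rep(got[4], 3))
  expect_false(got[1] == got[4])
  expect_identical(attr(res, "rounds"), 4L)     # n - k atomizations
  # greedy result attains the exhaustive best-GEV partition
  oracle <- oracle_best_partition(maps, 2)
  expect_equal(attr(res, "gev"), oracle$gev, tolerance = 1e-9)
})

test_that("k equal to the map count returns the maps themselves", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  res <- aahc_cluster(tset$maps, 4)
  expect_identical(attr(res, "rounds"), 0L)
  for (i in 1:4)
    expect_equal(spatial_correlation(res$maps[, i], tset$maps[, i]), 1)
  expect_error(aahc_cluster(tset$maps, 5), "1 <= k")
})

test_that("a map and its negation collapse to one polarity-invariant centroid", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  m <- tset$maps[, 1]
  res <- aahc_cluster(cbind(m, -m), 1)
  expect_equal(spatial_correlation(res$maps[, 1], m), 1)
  expect_equal(spatial_correlation(res$maps[, 1], -m), 1)
})

test_that("clustering decisions are invariant to sign flips and rescaling", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  maps <- fix_noisy_copies(tset$maps[, 1:3], per = 4, snr = 8, seed = 5)
  base <- attr(aahc_cluster(maps, 3), "assignment")
  set.seed(6)
  flips <- sample(c(-1, 1), ncol(maps), replace = TRUE)
  scales <- runif(ncol(maps), 0.5, 3)
  flipped <- sweep(maps, 2, flips * scales, "*")
  got <- attr(aahc_cluster(flipped, 3), "assignment")
  # same partition up to cluster relabeling
  expect_identical(unname(split(seq_along(base), base)[order(sapply(
    split(seq_along(base), base), min))]),
    unname(split(seq_along(got), got)[order(sapply(
      split(seq_along(got), got), min))]))
})

test_that("second-level clustering pools subjects faithfully", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  # degenerate pooling: identical subjects reproduce the shared maps
  subj <- replicate(4, tset, simplify = FALSE)
  grp <- group_templates(subj, 4, reference = tset)
  for (i in 1:4)
    expect_gte(spatial_correlation(grp$maps[, i], tset$maps[, i]), 0.999)
  expect_error(group_templates(subj[1], 4), "2 subjects")

  # noisy subjects, n = 20, SNR 10: mean recovery >= 0.95
  subj_noisy <- lapply(1:20, function(i) {
    noisy <- fix_noisy_copies(tset$maps, per = 1, snr = 10, seed = 100 + i)
    template_set(noisy, labels = paste0("M", 1:4), level = "subject")
  })
  grp2 <- group_templates(subj_noisy, 4, reference = tset)
  cors <- vapply(1:4, function(i)
    spatial_correlation(grp2$maps[, i], tset$maps[, i]), numeric(1))
  expect_gte(mean(cors), 0.95)

  # permuting subject order changes nothing up to label-preserving sign
  grp3 <- group_templates(rev(subj_noisy), 4, reference = tset)
  for (i in 1:4)
    expect_gte(spatial_correlation(grp3$maps[, i], grp2$maps[, i]), 0.999)
})

test_that("canonical labeling finds the optimal permutation", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  # already canonical: identity
  lab <- label_canonical(tset, tset)
  expect_identical(lab$labels, tset$labels)
  expect_equal(lab$maps, tset$maps, tolerance = 1e-12)
  # reversed input: permutation recovered
  rev_set <- template_set(tset$maps[, 4:1], labels = paste0("M", 1:4))
  lab2 <- label_canonical(rev_set, tset)
  expect_equal(lab2$maps, tset$maps, tolerance = 1e-12)
  # random sign flips leave the labeling unchanged
  set.seed(8)
  flipped <- template_set(sweep(tset$maps[, c(3, 1, 4, 2)], 2,
                                sample(c(-1, 1), 4, TRUE), "*"),
                          labels = paste0("M", 1:4))
  lab3 <- label_canonical(flipped, tset)
  for (i in 1:4)
    expect_gte(spatial_correlation(lab3$maps[, i], tset$maps[, i]), 0.999)
  expect_error(label_canonical(template_set(tset$maps[, 1:3]), tset),
               "mismatch")
})

test_that("AAHC beats sampled random merge paths in GEV", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  maps <- fix_noisy_copies(tset$maps, per = 3, snr = 6, seed = 9)
  res <- aahc_cluster(maps, 4)
  set.seed(10)
  for (i in 1:25) {
    random_assignment <- sample(1:4, ncol(maps), replace = TRUE)
    if (length(unique(random_assignment)) < 4) next
    expect_gte(attr(res, "gev") + 1e-12,
               oracle_partition_gev(maps, random_assignment))
  }
})
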