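test_that("noise-free template copies are labeled regardless of polarity", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  amps <- c(3, -2, 0.5, -0.1, 7, -4)
  rec <- fix_template_recording(tset, rep(2L, 6), amps)
  seg <- backfit(rec, tset)
  expect_identical(seg$labels, rep(2L, 6))
  expect_equal(unname(seg$correlations), rep(1, 6), tolerance = 1e-9)
})

test_that("exact argmax ties resolve to the lowest canonical label", {
  # two orthogonal unit maps; a sample equidistant from both
  maps <- cbind(A = c(1, -1, 0, 0, 0, 0, 0, 0) / sqrt(2),
                B = c(0, 0, 1, -1, 0, 0, 0, 0) / sqrt(2))
  tset <- template_set(maps, labels = c("A", "B"))
  sample_eq <- matrix(c(1, -1, 1, -1, 0, 0, 0, 0), 8, 1)
  rec <- eeg_recording(cbind(sample_eq, sample_eq), 500, fix_montage(8))
  seg1 <- backfit(rec, tset)
  seg2 <- backfit(rec, tset)
  expect_identical(seg1$labels, c(1L, 1L))
  expect_identical(seg1$labels, seg2$labels)   # deterministic across runs
})

test_that("zero-variance samples inherit the nearest label in their segment", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  rec <- fix_template_recording(tset, c(1L, 1L, 1L, 3L, 3L), rep(1, 5))
  rec$data[, 2] <- 0
  seg <- backfit(rec, tset)
  expect_identical(seg$labels, c(1L, 1L, 1L, 3L, 3L))
  expect_identical(seg$correlations[2], 0)
})

test_that("labels never bridge segment boundaries in run statistics", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  rec <- fix_template_recording(tset, rep(1L, 8), rep(1, 8))
  rec$segments <- cbind(start = c(0L, 4L), end = c(4L, 8L))
  seg <- backfit(rec, tset)
  runs <- label_runs(seg$labels, seg$segments, k = 4)
  expect_identical(nrow(runs), 2L)   # one run per segment, same class
  expect_true(all(runs$trunc_start & runs$trunc_end))
})

test_that("minimum-duration smoothing removes isolated blips", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  labels <- c(rep(1L, 20), 2L, rep(1L, 20), rep(3L, 25))
  rec <- fix_template_recording(tset, labels, rep(1, length(labels)))
  seg <- backfit(rec, tset, smooth_min_ms = 8)   # 4 samples at 500 Hz
  expect_identical(seg$labels[21], 1L)           # blip absorbed
  expect_identical(seg$labels[42:66], rep(3L, 25))  # long runs intact
  # without smoothing the blip survives (default off)
  seg0 <- backfit(rec, tset)
  expect_identical(seg0$labels[21], 2L)
})

test_that("GEV is 100% for perfect fits and partitions exactly by class", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  labels <- rep(1:4, each = 10)
  rec <- fix_template_recording(tset, labels, runif(40, 0.5, 2))
  seg <- backfit(rec, tset)
  gev <- compute_gev(rec, seg, tset)
  expect_equal(gev$total, 100, tolerance = 1e-9)
  expect_equal(sum(gev$per_class), gev$total, tolerance = 1e-9)
})

test_that("backfit labeling maximizes GEV over random relabelings", {
  sim <- simulate_recording(duration_s = 6, seed = 13)
  rec <- segment_recording(sim$recording, 2)
  tset <- sim$truth$templates
  seg <- backfit(rec, tset)
  base <- compute_gev(rec, seg, tset)$total
  set.seed(14)
  for (i in 1:100) {
    shuffled <- seg
    shuffled$labels <- sample(seg$labels)
    expect_lt(compute_gev(rec, shuffled, tset)$total, base)
  }
})

test_that("empty segmentations are rejected", {
  tset <- make_canonical_templates(fix_montage(16), 4)
  rec <- fix_template_recording(tset, c(1L, 2L), c(1, 1))
  seg <- backfit(rec, tset)
  seg$labels[] <- NA_integer_
  expect_error(compute_gev(rec, seg, tset), "empty")
})
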