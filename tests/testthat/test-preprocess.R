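sine_recording <- function(freq, fs = 500, dur = 4, n_ch = 8) {
  tt <- seq_len(fs * dur) / fs
  base <- sin(2 * pi * freq * tt)
  data <- outer(c(1, -1, rep(c(0.5, -0.5), length.out = n_ch - 2)), base)
  eeg_recording(data, fs, fix_montage(n_ch))
}

test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  rec10 <- sine_recording(10)
  out10 <- bandpass(rec10, 2, 20)
  mid <- 500:1500   # avoid filter edge transients
  gain <- max(abs(out10$data[1, mid])) / max(abs(rec10$data[1, mid]))
  expect_gte(gain, 0.89); expect_lte(gain, 1.12)

  rec40 <- sine_recording(40)
  out40 <- bandpass(rec40, 2, 20)
  atten <- max(abs(out40$data[1, mid])) / max(abs(rec40$data[1, mid]))
  expect_lt(20 * log10(atten), -20)
})

test_that("band-pass is linear and validates its band", {
  zeros <- eeg_recording(matrix(0, 8, 1000), 500, fix_montage(8))
  expect_equal(bandpass(zeros, 2, 20)$data, zeros$data)
  expect_error(bandpass(zeros, 2, 250), "Nyquist")
  expect_error(bandpass(zeros, 20, 2), "low_hz")
})

test_that("filtering never increases total energy on broadband input", {
  set.seed(9)
  rec <- eeg_recording(matrix(rnorm(8 * 4000), 8), 500, fix_montage(8))
  out <- bandpass(rec, 2, 20)
  expect_lt(sum(out$data^2), sum(rec$data^2))
})

test_that("downsampling halves the count, keeps DC and in-band amplitude", {
  m <- fix_montage(8)
  dc <- eeg_recording(matrix(3.7, 8, 7000), 1000, m)
  out <- downsample_recording(dc, 500)
  expect_identical(ncol(out$data), 3500L)
  expect_equal(out$fs_hz, 500)
  expect_lt(max(abs(out$data - 3.7)), 1e-9)

  tt <- seq_len(7000) / 1000
  sine <- eeg_recording(matrix(rep(sin(2 * pi * 10 * tt), each = 8), 8,
                               byrow = FALSE), 1000, m)
  ds <- downsample_recording(sine, 500)
  mid <- 500:3000
  expect_lt(abs(max(abs(ds$data[1, mid])) - 1), 0.01)
  expect_error(downsample_recording(dc, 2000), "exceed")
})

test_that("average reference zeroes channel means and is idempotent", {
  m <- fix_montage(8)
  rec <- eeg_recording(matrix(c(3, 1, rep(2, 6)), 8, 1), 500, m)
  out <- rereference_average(rec)
  expect_equal(out$data[1:2, 1], c(1, -1))
  set.seed(4)
  rnd <- eeg_recording(matrix(rnorm(32 * 1000), 32), 500, fix_montage(32))
  ref <- rereference_average(rnd)
  expect_lt(max(abs(colMeans(ref$data))), 1e-9)
  again <- rereference_average(ref)
  expect_lt(max(abs(again$data - ref$data)), 1e-12)
})

test_that("segmentation tiles the recording and drops the remainder", {
  m <- fix_montage(8)
  long <- eeg_recording(matrix(0, 8, 210000), 500, m)
  seg <- segment_recording(long, 2)
  expect_identical(nrow(seg$segments), 210L)
  expect_true(all(seg$segments[, 2] - seg$segments[, 1] == 1000L))

  short <- eeg_recording(matrix(0, 8, 2750), 500, m)   # 5.5 s
  seg2 <- segment_recording(short, 2)
  expect_identical(nrow(seg2$segments), 2L)
  expect_identical(max(seg2$segments), 2000L)           # 750 samples dropped

  tiny <- eeg_recording(matrix(0, 8, 500), 500, m)
  expect_error(segment_recording(tiny, 2), "shorter")
})

test_that("segments are half-open and non-overlapping for random durations", {
  m <- fix_montage(8)
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(1000:6000, 1)
    rec <- eeg_recording(matrix(0, 8, n), 500, m)
    seg <- segment_recording(rec, 1)$segments
    expect_true(all(seg[, 2] > seg[, 1]))
    if (nrow(seg) > 1)
      expect_true(all(seg[-1, 1] == seg[-nrow(seg), 2]))
    expect_lte(max(seg), n)
  }
})

test_that("the full conditioning chain emits a clean segmented recording", {
  sim <- simulate_recording(fs_hz = 1000, duration_s = 7, seed = 2)
  pp <- preprocess_eeg(sim$recording)
  expect_equal(pp$fs_hz, 500)
  expect_identical(ncol(pp$data), 3500L)
  expect_identical(nrow(pp$segments), 3L)
  expect_lt(max(abs(colMeans(pp$data))), 1e-9)
  expect_false(anyNA(pp$data))
  expect_identical(attr(pp, "config")$analysis_band, c(2, 20))
})

test_that("the ICA hook removes exactly the requested components", {
  set.seed(3)
  mixing <- matrix(rnorm(64), 8, 8)
  sources <- matrix(rnorm(8 * 200), 8)
  rec <- eeg_recording(mixing %*% sources, 500, fix_montage(8))
  clean <- apply_ica_removal(rec, solve(mixing), reject = 3L)
  kept <- sources; kept[3, ] <- 0
  expect_equal(clean$data, mixing %*% kept, tolerance = 1e-9)
})
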