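#' Validate a microstate transition matrix
#'
#' Conditional next-state probabilities: K x K, zero diagonal, every row
#' summing to 1 within 1e-12.
#' @param tm numeric matrix.
#' @return the matrix, invisibly, after validation.
#' @export
validate_transition_matrix <- function(tm) {
  tm <- as.matrix(tm)
  if (nrow(tm) != ncol(tm)) stop("transition matrix must be square")
  if (any(tm < 0)) stop("transition probabilities must be >= 0")
  if (any(diag(tm) != 0)) stop("transition matrix diagonal must be exactly 0")
  if (any(abs(rowSums(tm) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1 (within 1e-12)")
  invisible(tm)
}

#' Ground truth bundle for a synthesized recording
#'
#' Everything downstream recovery tests compare against: the generating
#' templates, the per-sample state sequence, the conditional transition
#' matrix, per-class mean dwell times and the linear SNR.
#'
#' @param templates a [template_set].
#' @param state_sequence integer per-sample labels in 1..K.
#' @param transition_matrix K x K conditional matrix (zero diagonal).
#' @param mean_durations_ms per-class positive dwell means (ms).
#' @param snr linear signal-to-noise ratio.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(templates, state_sequence, transition_matrix,
                         mean_durations_ms, snr) {
  validate_transition_matrix(transition_matrix)
  k <- ncol(templates$maps)
  if (any(state_sequence < 1L | state_sequence > k))
    stop("state_sequence labels out of range")
  if (any(mean_durations_ms <= 0)) stop("mean durations must be positive")
  structure(list(templates = templates,
                 state_sequence = as.integer(state_sequence),
                 transition_matrix = transition_matrix,
                 mean_durations_ms = mean_durations_ms, snr = snr),
            class = "ground_truth")
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Successor states follow `transition_matrix`; dwell times are drawn per
#' class from a gamma law with the stated mean and fixed shape (default 4,
#' coefficient of variation 0.5, matching the duration SD/mean ratios
#' typical of resting-state microstate statistics), or from a geometric
#' law for Markov-exact tests. The last run is truncated at the requested
#' length.
#'
#' @param transition_matrix K x K conditional matrix, zero diagonal,
#'   rows summing to 1.
#' @param mean_durations_ms per-class mean dwell times (ms); each must be
#'   at least 2 samples long at `fs_hz`.
#' @param fs_hz sampling rate (Hz).
#' @param duration_s sequence duration (s).
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @param dwell `"gamma"` (default) or `"geometric"`.
#' @param shape gamma shape parameter (default 4).
#' @return integer vector of length `round(fs_hz * duration_s)` with
#'   labels in 1..K.
#' @export
simulate_state_sequence <- function(transition_matrix, mean_durations_ms,
                                    fs_hz, duration_s, seed = NULL,
                                    dwell = c("gamma", "geometric"),
                                    shape = 4) {
  validate_transition_matrix(transition_matrix)
  dwell <- match.arg(dwell)
  k <- nrow(transition_matrix)
  if (length(mean_durations_ms) == 1L)
    mean_durations_ms <- rep(mean_durations_ms, k)
  if (length(mean_durations_ms) != k)
    stop("need one mean duration per class")
  if (fs_hz <= 0 || duration_s <= 0) stop("fs_hz and duration_s must be > 0")
  mean_samples <- mean_durations_ms * fs_hz / 1000
  if (any(mean_samples < 2))
    stop("mean duration below 2 samples at this sampling rate")
  if (!is.null(seed)) set.seed(seed)
  n <- round(fs_hz * duration_s)
  out <- integer(n)
  state <- sample.int(k, 1L)
  filled <- 0L
  while (filled < n) {
    len <- switch(dwell,
      gamma = max(1L, as.integer(round(stats::rgamma(
        1L, shape = shape, scale = mean_samples[state] / shape)))),
      geometric = 1L + stats::rgeom(1L, prob = 1 / mean_samples[state]))
    len <- min(len, n - filled)
    out[(filled + 1L):(filled + len)] <- state
    filled <- filled + len
    state <- sample.int(k, 1L, prob = transition_matrix[state, ])
  }
  out
}

#' Synthesize multichannel EEG from a microstate sequence
#'
#' Each sample is `envelope(t) * template(label(t))` plus spatially white
#' Gaussian noise scaled so that RMS(signal)/RMS(noise) over the whole
#' recording equals `snr`. The envelope is a rectified sinusoid (default
#' 10 Hz, alpha-like) with a 10% amplitude floor, so global field power
#' shows ~2 x `envelope_freq_hz` local maxima per second -- the moments
#' of highest field intensity the peak-based clustering relies on. The
#' output is average-referenced at every sample.
#'
#' @param states integer per-sample labels in 1..K.
#' @param templates a [template_set] with K maps.
#' @param fs_hz sampling rate (Hz).
#' @param snr linear signal-to-noise ratio (> 0).
#' @param envelope_freq_hz envelope frequency (default 10).
#' @param seed optional integer seed.
#' @param envelope_floor minimum envelope amplitude (default 0.1).
#' @return An [eeg_recording] (unsegmented).
#' @export
synthesize_eeg <- function(states, templates, fs_hz, snr,
                           envelope_freq_hz = 10, seed = NULL,
                           envelope_floor = 0.1) {
  if (snr <= 0) stop("snr must be positive")
  k <- ncol(templates$maps)
  if (any(states < 1L | states > k)) stop("state labels out of range")
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  tt <- (seq_len(n) - 1L) / fs_hz
  env <- pmax(abs(sin(2 * pi * envelope_freq_hz * tt)), envelope_floor)
  sig <- templates$maps[, states, drop = FALSE] *
    rep(env, each = nrow(templates$maps))
  sd_noise <- sqrt(mean(sig^2)) / snr
  data <- sig + matrix(stats::rnorm(length(sig), sd = sd_noise),
                       nrow(sig), ncol(sig))
  data <- sweep(data, 2L, colMeans(data))   # average reference per sample
  mtg <- montage(paste0("E", seq_len(nrow(data))),
                 make_disk_montage(max(8L, nrow(data)))$positions[
                   seq_len(nrow(data)), , drop = FALSE])
  eeg_recording(data, fs_hz, mtg)
}

#' Simulate a ground-truth-labeled synthetic recording
#'
#' Convenience wrapper: canonical templates on a disk montage, a
#' semi-Markov label sequence, and topography synthesis, returned with
#' the full [ground_truth] bundle.
#'
#' @inheritParams simulate_state_sequence
#' @inheritParams synthesize_eeg
#' @param n_channels montage size (default 32).
#' @param k number of states (default 4).
#' @param transition_matrix optional; default uniform off-diagonal.
#' @return list with elements `recording` and `truth`.
#' @export
simulate_recording <- function(n_channels = 32L, k = 4L,
                               transition_matrix = NULL,
                               mean_durations_ms = c(65, 62, 66, 66),
                               fs_hz = 500, duration_s = 60, snr = 4,
                               envelope_freq_hz = 10, seed = NULL,
                               dwell = c("gamma", "geometric")) {
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k)
    diag(transition_matrix) <- 0
  }
  mtg <- make_disk_montage(n_channels)
  tset <- make_canonical_templates(mtg, k)
  if (!is.null(seed)) set.seed(seed)
  states <- simulate_state_sequence(transition_matrix, mean_durations_ms,
                                    fs_hz, duration_s, seed = NULL,
                                    dwell = match.arg(dwell))
  rec <- synthesize_eeg(states, tset, fs_hz, snr,
                        envelope_freq_hz = envelope_freq_hz, seed = NULL)
  rec$montage <- mtg
  list(recording = rec,
       truth = ground_truth(tset, states, transition_matrix,
                            mean_durations_ms, snr))
}
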