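#' Multichannel EEG recording container
#'
#' Carrier object through the preprocessing chain: a channels x samples
#' matrix in microvolts, a sampling rate, a [montage], and optional
#' half-open segment boundaries (0-based, `[start, end)`), which later
#' statistics never bridge.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs_hz sampling rate in Hz.
#' @param montage a [montage] with one entry per data row.
#' @param segments optional integer matrix with columns `start`, `end`
#'   (0-based, half-open); `NULL` means not yet segmented.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, montage, segments = NULL) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (!all(is.finite(data))) stop("recording contains NaN/Inf")
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (nrow(data) != n_channels(montage))
    stop("data rows must match montage channel count")
  if (!is.null(segments)) segments <- validate_segments(segments, ncol(data))
  structure(
    list(data = data, fs_hz = fs_hz, montage = montage, segments = segments),
    class = "eeg_recording"
  )
}

validate_segments <- function(segments, n_samples) {
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  if (any(segments[, 1L] < 0L) || any(segments[, 2L] > n_samples))
    stop("segments out of bounds")
  if (any(segments[, 2L] <= segments[, 1L]))
    stop("segments must be non-empty half-open intervals")
  o <- order(segments[, 1L])
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1L &&
      any(segments[-1L, 1L] < segments[-nrow(segments), 2L]))
    stop("segments overlap")
  segments
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d ch x %d samples @ %g Hz, %s>\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              if (is.null(x$segments)) "unsegmented"
              else sprintf("%d segments", nrow(x$segments))))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration_s <- function(rec) ncol(rec$data) / rec$fs_hz

# Segment index for every sample (NA outside all segments). If the
# recording is unsegmented, the whole recording is one segment.
sample_segment_index <- function(rec) {
  n <- ncol(rec$data)
  seg <- rep(NA_integer_, n)
  segments <- rec$segments
  if (is.null(segments)) segments <- cbind(start = 0L, end = n)
  for (i in seq_len(nrow(segments)))
    seg[(segments[i, 1L] + 1L):segments[i, 2L]] <- i
  seg
}
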