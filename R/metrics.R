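#' Run-length encoding of a label sequence within segments
#'
#' Maximal constant-label runs that never cross a segment boundary.
#' Runs touching a segment edge are flagged truncated on that side
#' (their true duration is unobserved there). NA labels (unassigned
#' samples) break runs and produce no run themselves.
#'
#' @param labels integer per-sample labels (NA = unassigned).
#' @param segments half-open segment matrix (0-based); `NULL` treats the
#'   sequence as one segment.
#' @param k number of classes (default `max(labels)`).
#' @return data.frame with columns `class`, `start` (0-based), `length`
#'   (samples), `segment`, `trunc_start`, `trunc_end`; attribute `k` and
#'   `n_labeled` (total labeled samples).
#' @export
label_runs <- function(labels, segments = NULL, k = NULL) {
  n <- length(labels)
  if (is.null(segments)) segments <- cbind(start = 0L, end = n)
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  out <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    lo <- segments[s, 1L] + 1L; hi <- segments[s, 2L]
    lab <- labels[lo:hi]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    if (!any(keep)) next
    out[[s]] <- data.frame(
      class = r$values[keep],
      start = lo - 1L + starts[keep] - 1L,
      length = r$lengths[keep],
      segment = s,
      trunc_start = starts[keep] == 1L,
      trunc_end = ends[keep] == (hi - lo + 1L)
    )
  }
  runs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(runs))
    runs <- data.frame(class = integer(0), start = integer(0),
                       length = integer(0), segment = integer(0),
                       trunc_start = logical(0), trunc_end = logical(0))
  attr(runs, "k") <- k
  attr(runs, "n_labeled") <- sum(!is.na(labels))
  runs
}

#' Per-class mean microstate duration
#'
#' Average run duration in ms over complete (non-truncated) runs; a class
#' with no complete run yields NA. Truncated runs are excluded because
#' their true dwell time is censored by the segment edge.
#'
#' @param runs output of [label_runs].
#' @param fs_hz sampling rate (Hz).
#' @return named numeric vector, one ms value per class.
#' @export
mean_duration <- function(runs, fs_hz) {
  if (nrow(runs) == 0L) stop("no runs: mean duration undefined")
  k <- attr(runs, "k")
  complete <- runs[!runs$trunc_start & !runs$trunc_end, , drop = FALSE]
  out <- vapply(seq_len(k), function(cl) {
    len <- complete$length[complete$class == cl]
    if (length(len) == 0L) NA_real_ else mean(len) / fs_hz * 1000
  }, numeric(1))
  names(out) <- LETTERS[seq_len(k)]
  out
}

#' Per-class time coverage
#'
#' Percentage of labeled analysis time spent in each class; truncated
#' runs count in full (time spent is time spent). Sums to 100 over
#' classes.
#'
#' @param runs output of [label_runs].
#' @param total_samples total labeled samples (default from `runs`).
#' @return named percentage vector.
#' @export
coverage <- function(runs, total_samples = attr(runs, "n_labeled")) {
  if (is.null(total_samples) || total_samples <= 0)
    stop("total_samples must be positive")
  k <- attr(runs, "k")
  out <- vapply(seq_len(k), function(cl)
    sum(runs$length[runs$class == cl]) / total_samples * 100, numeric(1))
  names(out) <- LETTERS[seq_len(k)]
  out
}

#' Per-class occurrence rate
#'
#' Appearances per second: number of runs of the class whose onset was
#' observed (runs truncated at their start are not counted, since their
#' appearance happened before the analysis window) divided by the labeled
#' duration in seconds.
#'
#' @param runs output of [label_runs].
#' @param total_duration_s labeled duration in seconds (default from
#'   `runs` and `fs_hz`).
#' @param fs_hz sampling rate, used for the default duration.
#' @return named rate vector (/s).
#' @export
occurrence <- function(runs, total_duration_s = NULL, fs_hz = NULL) {
  if (is.null(total_duration_s)) {
    if (is.null(fs_hz)) stop("supply total_duration_s or fs_hz")
    total_duration_s <- attr(runs, "n_labeled") / fs_hz
  }
  if (total_duration_s <= 0) stop("total_duration_s must be positive")
  k <- attr(runs, "k")
  onset <- runs[!runs$trunc_start, , drop = FALSE]
  out <- vapply(seq_len(k), function(cl)
    sum(onset$class == cl) / total_duration_s, numeric(1))
  names(out) <- LETTERS[seq_len(k)]
  out
}

#' Joint transition probabilities between microstate classes
#'
#' Change events are consecutive runs within a segment (never across a
#' boundary). Each ordered pair i -> j (i != j) gets its count divided by
#' the total number of change events, so all `k*(k-1)` entries sum to 1
#' (the joint convention; see [conditional_transition_matrix] for the
#' row-conditional view).
#'
#' @param runs output of [label_runs].
#' @return named vector of `k*(k-1)` probabilities (names like `"A>B"`),
#'   with attribute `n_transitions`.
#' @export
transition_probabilities <- function(runs) {
  k <- attr(runs, "k")
  counts <- matrix(0, k, k)
  for (s in unique(runs$segment)) {
    cl <- runs$class[runs$segment == s]
    if (length(cl) >= 2L) {
      from <- cl[-length(cl)]; to <- cl[-1L]
      for (i in seq_along(from)) counts[from[i], to[i]] <-
          counts[from[i], to[i]] + 1
    }
  }
  total <- sum(counts)
  if (total == 0) stop("no transitions observed")
  pairs <- which(diag(k) == 0, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  out <- counts[pairs] / total
  names(out) <- paste0(LETTERS[pairs[, 1L]], ">", LETTERS[pairs[, 2L]])
  attr(out, "n_transitions") <- as.integer(total)
  out
}

#' Row-conditional transition matrix from joint probabilities
#'
#' Renormalizes the joint ordered-pair probabilities so each row sums
#' to 1 (zero diagonal), recovering the conditional next-state matrix a
#' semi-Markov generator is parameterized by.
#'
#' @param trans joint probabilities from [transition_probabilities].
#' @param k number of classes.
#' @return k x k conditional matrix.
#' @export
conditional_transition_matrix <- function(trans, k = 4L) {
  m <- matrix(0, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  pairs <- which(diag(k) == 0, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  m[pairs] <- trans
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  sweep(m, 1L, rs, "/")
}

#' All temporal microstate features of one segmentation
#'
#' The per-subject feature bundle the group statistics and the classifier
#' consume: per-class mean duration, coverage, occurrence, plus the
#' `k*(k-1)` joint transition probabilities.
#'
#' @param segmentation a [segmentation] from [backfit].
#' @return An object of class `microstate_features`: list with
#'   `duration_ms`, `coverage_pct`, `occurrence_hz`, `transitions`,
#'   `n_transitions`.
#' @export
microstate_features <- function(segmentation) {
  k <- length(segmentation$template_labels)
  runs <- label_runs(segmentation$labels, segmentation$segments, k = k)
  trans <- transition_probabilities(runs)
  structure(list(
    duration_ms = mean_duration(runs, segmentation$fs_hz),
    coverage_pct = coverage(runs),
    occurrence_hz = occurrence(runs, fs_hz = segmentation$fs_hz),
    transitions = trans,
    n_transitions = attr(trans, "n_transitions")
  ), class = "microstate_features")
}

#' Flatten microstate features to a named numeric row
#'
#' Fixed column order (durations, coverages, occurrences, transitions) so
#' feature tables are reproducible across runs and machines.
#'
#' @param f a `microstate_features` object.
#' @return named numeric vector.
#' @export
feature_row <- function(f) {
  c(stats::setNames(f$duration_ms, paste0("dur_", names(f$duration_ms))),
    stats::setNames(f$coverage_pct, paste0("cov_", names(f$coverage_pct))),
    stats::setNames(f$occurrence_hz, paste0("occ_", names(f$occurrence_hz))),
    stats::setNames(as.numeric(f$transitions),
                    paste0("t_", sub(">", "", names(f$transitions)))))
}
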