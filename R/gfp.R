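#' Global field power
#'
#' GFP at each sample is the spatial (population, 1/N) standard deviation
#' of the scalp potential across channels -- the instantaneous field
#' strength whose local maxima mark the moments of highest topographic
#' signal-to-noise. Input should be average-referenced; if not, it is
#' corrected with a warning (the GFP value is identical either way, but
#' downstream topographic work assumes the reference).
#'
#' @param rec an [eeg_recording], or a channels x samples matrix.
#' @return numeric vector of per-sample GFP values (microvolts).
#' @export
compute_gfp <- function(rec) {
  data <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  mu <- colMeans(data)
  if (max(abs(mu)) > 1e-6) {
    warning("input not average-referenced; correcting before GFP")
    data <- sweep(data, 2L, mu)
    mu <- rep(0, ncol(data))
  }
  sqrt(colMeans(data^2) - mu^2)
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP series, found per segment so peaks
#' never straddle a segment boundary; segment endpoints are never peaks.
#' When two maxima fall within `min_separation_ms`, the larger survives
#' (greedy, by descending GFP). `min_separation_ms = 0` gives the pure
#' local-maximum rule.
#'
#' @param gfp numeric GFP vector.
#' @param fs_hz sampling rate (Hz).
#' @param min_separation_ms minimum peak spacing (default 10 ms).
#' @param segments optional half-open segment matrix (0-based); `NULL`
#'   treats the series as one segment.
#' @return ascending integer sample indices (1-based).
#' @export
find_gfp_peaks <- function(gfp, fs_hz, min_separation_ms = 10,
                           segments = NULL) {
  n <- length(gfp)
  if (is.null(segments)) segments <- cbind(start = 0L, end = n)
  min_gap <- min_separation_ms / 1000 * fs_hz
  peaks <- integer(0)
  for (s in seq_len(nrow(segments))) {
    lo <- segments[s, 1L] + 1L; hi <- segments[s, 2L]
    if (hi - lo < 2L) next
    v <- gfp[lo:hi]
    if (max(v) - min(v) < .Machine$double.eps * max(abs(v), 1)) next  # flat
    i <- 2:(length(v) - 1L)
    cand <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
    if (length(cand) == 0L) next
    if (min_gap > 0 && length(cand) > 1L) {
      keep <- integer(0)
      for (p in cand[order(v[cand], decreasing = TRUE)]) {
        if (all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
      }
      cand <- sort(keep)
    }
    peaks <- c(peaks, cand + lo - 1L)
  }
  sort(unname(peaks))
}

#' Spatial correlation between two topography maps
#'
#' Pearson correlation across channels; with `polarity_invariant = TRUE`
#' (the convention used throughout clustering and backfitting) the
#' absolute value is returned, so a map and its negation correlate at 1.
#'
#' @param u,v numeric channel vectors of equal length.
#' @param polarity_invariant return `|r|` (default TRUE).
#' @return correlation in `[0, 1]` (or `[-1, 1]` when not invariant).
#' @export
spatial_correlation <- function(u, v, polarity_invariant = TRUE) {
  if (length(u) != length(v)) stop("maps must share the channel dimension")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("spatial correlation undefined for a zero-variance map")
  r <- stats::cor(u, v)
  if (polarity_invariant) abs(r) else r
}

# Center each column and scale to unit norm; columns with zero variance
# become NA columns (callers decide how to handle them).
.normalize_maps <- function(maps) {
  maps <- sweep(maps, 2L, colMeans(maps))
  nrm <- sqrt(colSums(maps^2))
  nrm[nrm == 0] <- NA_real_
  sweep(maps, 2L, nrm, "/")
}
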