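#' Backfit templates into a recording
#'
#' Labels every in-segment sample with the template of maximal absolute
#' spatial correlation (exact argmax ties go to the lowest canonical
#' label, deterministically). Two labeling modes are provided:
#'
#' * `"sample"` -- the direct per-sample argmax (default; no temporal
#'   prior at all).
#' * `"peak_interp"` -- only GFP peaks are labeled by correlation and
#'   every sample inherits the label of its nearest peak within the
#'   segment (ties to the earlier peak); segments without any peak fall
#'   back to per-sample labeling. This is the classical peak-based
#'   convention and is far more robust at low instantaneous SNR.
#'
#' Optional minimum-duration smoothing (`smooth_min_ms > 0`) iteratively
#' reassigns runs shorter than the threshold to whichever neighbouring
#' run's template correlates better over the short run's samples; off by
#' default.
#'
#' Zero-variance samples cannot be correlated; they inherit the label of
#' the nearest labeled sample in their segment and get correlation 0.
#'
#' @param rec a preprocessed [eeg_recording] (average-referenced,
#'   segmented; unsegmented input is treated as one segment).
#' @param templates a [template_set].
#' @param mode `"sample"` or `"peak_interp"`.
#' @param smooth_min_ms minimum run duration in ms (0 = no smoothing).
#' @param min_peak_separation_ms peak spacing for `"peak_interp"`.
#' @return An object of class `segmentation`: per-sample `labels`
#'   (template index, NA outside segments), `correlations` (absolute
#'   spatial correlation with the assigned template), `gfp`, `fs_hz`,
#'   `segments`, and the template labels.
#' @export
backfit <- function(rec, templates, mode = c("sample", "peak_interp"),
                    smooth_min_ms = 0, min_peak_separation_ms = 10) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(templates, "template_set"))
  mode <- match.arg(mode)
  n <- ncol(rec$data)
  k <- ncol(templates$maps)
  segments <- rec$segments
  if (is.null(segments)) segments <- cbind(start = 0L, end = n)

  gfp <- compute_gfp(rec)
  norm <- .normalize_maps(rec$data)          # NA columns at zero variance
  zerovar <- which(is.na(norm[1L, ]))
  # templates are centered unit-norm, samples centered unit-norm:
  # Pearson across channels reduces to the plain dot product
  cors <- abs(crossprod(templates$maps, norm)) # k x n, NA at zerovar

  labels <- rep(NA_integer_, n)
  in_seg <- !is.na(sample_segment_index(rec))

  if (mode == "sample") {
    ok <- in_seg & !is.na(cors[1L, ])
    labels[ok] <- max.col(t(cors[, ok, drop = FALSE]), ties.method = "first")
  } else {
    peaks <- find_gfp_peaks(gfp, rec$fs_hz,
                            min_separation_ms = min_peak_separation_ms,
                            segments = segments)
    peak_lab <- max.col(t(cors[, peaks, drop = FALSE]), ties.method = "first")
    for (s in seq_len(nrow(segments))) {
      lo <- segments[s, 1L] + 1L; hi <- segments[s, 2L]
      pk <- which(peaks >= lo & peaks <= hi)
      idx <- lo:hi
      if (length(pk) == 0L) {   # fallback: per-sample argmax
        okc <- !is.na(cors[1L, idx])
        labels[idx[okc]] <-
          max.col(t(cors[, idx[okc], drop = FALSE]), ties.method = "first")
        next
      }
      nearest <- vapply(idx, function(i) {
        d <- abs(peaks[pk] - i)
        pk[which.min(d)]        # which.min takes the earlier peak on ties
      }, integer(1))
      labels[idx] <- peak_lab[nearest]
    }
  }

  # zero-variance samples: nearest labeled neighbour within the segment
  if (length(zerovar) > 0L) {
    seg_of <- sample_segment_index(rec)
    for (i in intersect(zerovar, which(in_seg))) {
      idx <- which(seg_of == seg_of[i] & !is.na(labels))
      idx <- setdiff(idx, i)
      if (length(idx) > 0L) labels[i] <- labels[idx[which.min(abs(idx - i))]]
    }
  }

  if (smooth_min_ms > 0)
    labels <- .smooth_min_duration(labels, cors, segments,
                                   min_len = smooth_min_ms / 1000 * rec$fs_hz)

  corr_assigned <- rep(NA_real_, n)
  okl <- which(!is.na(labels) & !is.na(cors[1L, ]))
  corr_assigned[okl] <- cors[cbind(labels[okl], okl)]
  corr_assigned[intersect(zerovar, which(!is.na(labels)))] <- 0

  structure(list(labels = labels, correlations = corr_assigned, gfp = gfp,
                 fs_hz = rec$fs_hz, segments = segments,
                 template_labels = templates$labels),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation: %d samples @ %g Hz, %d classes, %d segments>\n",
              length(x$labels), x$fs_hz, length(x$template_labels),
              nrow(x$segments)))
  invisible(x)
}

# Reassign runs shorter than min_len samples to the better-correlating
# neighbouring run label, whole-run-at-a-time, until stable.
.smooth_min_duration <- function(labels, cors, segments, min_len,
                                 max_iter = 20L) {
  min_len <- ceiling(min_len)
  for (s in seq_len(nrow(segments))) {
    lo <- segments[s, 1L] + 1L; hi <- segments[s, 2L]
    lab <- labels[lo:hi]
    if (all(is.na(lab))) next
    for (iter in seq_len(max_iter)) {
      r <- rle(lab)
      if (length(r$lengths) <= 1L) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      short <- which(r$lengths < min_len & !is.na(r$values))
      if (length(short) == 0L) break
      # shortest first so isolated blips dissolve before longer runs
      short <- short[order(r$lengths[short])]
      changed <- FALSE
      for (j in short) {
        idx <- starts[j]:ends[j]
        prev_lab <- if (j > 1L) r$values[j - 1L] else NA_integer_
        next_lab <- if (j < length(r$values)) r$values[j + 1L] else NA_integer_
        cand <- stats::na.omit(unique(c(prev_lab, next_lab)))
        if (length(cand) == 0L) next
        score <- vapply(cand, function(l)
          mean(cors[l, lo + idx - 1L], na.rm = TRUE), numeric(1))
        new_lab <- cand[which.max(score)]
        if (!identical(new_lab, r$values[j])) {
          lab[idx] <- new_lab
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    labels[lo:hi] <- lab
  }
  labels
}

#' Global explained variance of a segmentation
#'
#' GEV is the share of GFP-weighted topographic variance explained by
#' assigning each labeled sample to its template:
#' `sum_t (GFP_t * corr(v_t, map_label(t)))^2 / sum_t GFP_t^2`, reported
#' in percent. Per-class GEV restricts the numerator to that class's
#' samples, so the per-class values partition the total exactly.
#'
#' @param rec the recording the segmentation came from.
#' @param segmentation a [segmentation] from [backfit].
#' @param templates the [template_set] used for backfitting.
#' @return list with `total` (percent) and `per_class` (named percent
#'   vector summing to `total`).
#' @export
compute_gev <- function(rec, segmentation, templates) {
  labels <- segmentation$labels
  ok <- which(!is.na(labels))
  if (length(ok) == 0L) stop("empty segmentation: GEV undefined")
  norm <- .normalize_maps(rec$data)
  cors <- abs(crossprod(templates$maps, norm))
  gfp <- segmentation$gfp
  num <- (gfp[ok] * cors[cbind(labels[ok], ok)])^2
  num[is.na(num)] <- 0                      # zero-variance samples
  denom <- sum(gfp[ok]^2)
  per_class <- vapply(seq_len(ncol(templates$maps)), function(cl)
    sum(num[labels[ok] == cl]) / denom * 100, numeric(1))
  names(per_class) <- templates$labels
  list(total = sum(num) / denom * 100, per_class = per_class)
}
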