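#' Electrode montage on the unit disk
#'
#' A montage is the minimal sensor-geometry object the pipeline needs:
#' unique channel identifiers plus 2-D positions on (or inside) the unit
#' disk, nose pointing along +y. Positions are used for canonical template
#' construction and for inverse-distance bad-channel interpolation; no
#' 3-D head geometry is modelled.
#'
#' @param channel_ids character vector of unique channel names.
#' @param positions numeric matrix, one row per channel, columns x and y,
#'   finite, nominally within the unit disk.
#' @return An object of class `montage`.
#' @export
montage <- function(channel_ids, positions) {
  positions <- as.matrix(positions)
  if (length(channel_ids) < 8L)
    stop("a montage needs at least 8 channels")
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  if (nrow(positions) != length(channel_ids) || ncol(positions) != 2L)
    stop("positions must be a (n_channels x 2) matrix")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  structure(
    list(channel_ids = as.character(channel_ids), positions = positions),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage: %d channels on unit disk>\n", length(x$channel_ids)))
  invisible(x)
}

#' Number of channels in a montage
#' @param m a `montage`.
#' @return integer channel count.
#' @export
n_channels <- function(m) length(m$channel_ids)

#' Build a synthetic scalp montage on concentric rings
#'
#' Deterministic layout: one central electrode (when the count allows),
#' the remainder spread over concentric rings of radius r = i/n_rings with
#' evenly spaced angles, ring phase alternating so columns do not align.
#' This emulates the geometry of commercial dense-array caps well enough
#' for topographic work at desk scale; channel counts from 8 to 256 are
#' supported.
#'
#' @param n_channels integer >= 8.
#' @return A `montage` with channels named E1..En.
#' @export
make_disk_montage <- function(n_channels) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 8L) stop("need at least 8 channels")
  n_rings <- max(2L, ceiling(sqrt(n_channels / 3)))
  # distribute channels over rings proportionally to circumference
  remaining <- n_channels - 1L           # one electrode at the vertex
  weights <- seq_len(n_rings)
  counts <- floor(remaining * weights / sum(weights))
  # hand out the remainder from the outermost ring inwards
  deficit <- remaining - sum(counts)
  if (deficit > 0L) {
    idx <- rev(seq_len(n_rings))[seq_len(deficit)]
    counts[idx] <- counts[idx] + 1L
  }
  xs <- 0; ys <- 0
  for (i in seq_len(n_rings)) {
    m <- counts[i]
    if (m == 0L) next
    r <- i / n_rings * 0.95
    phase <- (i %% 2L) * pi / m
    theta <- 2 * pi * (seq_len(m) - 1L) / m + phase
    xs <- c(xs, r * sin(theta))
    ys <- c(ys, r * cos(theta))
  }
  pos <- cbind(x = xs, y = ys)
  montage(paste0("E", seq_len(n_channels)), pos)
}

#' Interpolate bad channels by inverse-distance weighting
#'
#' Replaces flagged channels with the inverse-distance-weighted mean of the
#' good channels on the montage plane. Channels can be flagged explicitly
#' or by a simple amplitude/flatline screen (absolute amplitude above
#' `amp_uV` at any sample, or standard deviation below `flat_sd`).
#'
#' @param rec an `eeg_recording`.
#' @param bad integer or character indices of channels to interpolate;
#'   if `NULL`, channels are flagged by the screen.
#' @param amp_uV amplitude threshold for the screen (default 500).
#' @param flat_sd flatline threshold for the screen (default 1e-9).
#' @param power inverse-distance exponent (default 2).
#' @return The recording with flagged channels replaced.
#' @export
interpolate_bad_channels <- function(rec, bad = NULL, amp_uV = 500,
                                     flat_sd = 1e-9, power = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(bad)) bad <- match(bad, rec$montage$channel_ids)
  if (is.null(bad)) {
    sds <- apply(rec$data, 1L, stats::sd)
    maxs <- apply(abs(rec$data), 1L, max)
    bad <- which(maxs > amp_uV | sds < flat_sd)
  }
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0L) return(rec)
  good <- setdiff(seq_len(nrow(rec$data)), bad)
  if (length(good) < 2L) stop("too few good channels to interpolate from")
  pos <- rec$montage$positions
  for (b in bad) {
    d <- sqrt(rowSums((pos[good, , drop = FALSE] -
                         matrix(pos[b, ], length(good), 2, byrow = TRUE))^2))
    w <- 1 / pmax(d, 1e-6)^power
    w <- w / sum(w)
    rec$data[b, ] <- as.numeric(w %*% rec$data[good, , drop = FALSE])
  }
  rec
}
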