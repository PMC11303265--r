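#' Microstate template set
#'
#' K topography maps, each average-referenced (zero channel mean) and
#' unit norm, with unique labels. `level` records whether the maps came
#' from a single subject's clustering or from the second-level group
#' clustering.
#'
#' @param maps numeric matrix, channels x K.
#' @param labels character vector of K unique labels (canonically
#'   `A`, `B`, `C`, `D`, ...).
#' @param level `"subject"` or `"group"`.
#' @return An object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL,
                         level = c("subject", "group")) {
  maps <- as.matrix(maps)
  level <- match.arg(level)
  k <- ncol(maps)
  if (is.null(labels)) labels <- LETTERS[seq_len(k)]
  if (length(labels) != k || anyDuplicated(labels))
    stop("labels must be unique, one per map")
  maps <- apply(maps, 2L, function(m) {
    m <- m - mean(m)
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) stop("zero-variance template map")
    m / nrm
  })
  colnames(maps) <- labels
  structure(list(maps = maps, labels = labels, level = level),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set (%s level): %d maps [%s] on %d channels>\n",
              x$level, length(x$labels), paste(x$labels, collapse = ","),
              nrow(x$maps)))
  invisible(x)
}

#' Analytic canonical microstate templates
#'
#' Builds k reference topographies on a montage, deterministically from
#' the electrode geometry. For k = 4 the raw maps carry the canonical
#' orientation structure of the classic resting-state classes: two
#' mirror-symmetric oblique gradients (A: right-frontal to left-posterior,
#' B: left-frontal to right-posterior), one anterior-posterior gradient
#' (C), and one central radial map (D). For other k, gradients at evenly
#' spaced orientations are used, with the radial map appended from k >= 4.
#' The raw maps are then symmetrically (Loewdin) orthogonalised so all
#' pairwise spatial correlations are ~0 (<= 0.5 is guaranteed), while each
#' output map stays maximally close to its raw, named orientation --
#' canonical labeling therefore remains unambiguous.
#'
#' @param montage a [montage].
#' @param k number of templates (>= 2, <= channels - 1).
#' @return A `template_set` at group level with labels A, B, C, ...
#' @export
make_canonical_templates <- function(montage, k = 4L) {
  k <- as.integer(k)
  nc <- n_channels(montage)
  if (k < 2L) stop("k must be >= 2")
  if (k > nc - 1L)
    stop("k must be <= channels - 1 for linearly independent maps")
  x <- montage$positions[, 1L]
  y <- montage$positions[, 2L]
  r2 <- x^2 + y^2
  gradient <- function(angle_deg) {
    a <- angle_deg * pi / 180
    sin(a) * x + cos(a) * y
  }
  raw <- if (k == 4L) {
    # oblique axes at +-60 deg from the midline keep raw pairwise
    # correlations near 0.5 on an isotropic layout before
    # orthogonalisation; C is a curved anterior-posterior pattern so the
    # three non-radial maps are linearly independent
    cbind(A = gradient(-60), B = gradient(60), C = y * abs(y),
          D = 1 - 2 * r2)
  } else {
    # disk-harmonic basis: angular harmonics of increasing order plus
    # radial terms, pairwise independent on a generic layout
    basis <- list(x, y, x^2 - y^2, 2 * x * y, 1 - 2 * r2,
                  x * (x^2 - 3 * y^2), y * (3 * x^2 - y^2),
                  r2 * (1 - 2 * r2), x * (1 - 2 * r2), y * (1 - 2 * r2))
    if (k > length(basis)) stop("k too large for the analytic basis")
    do.call(cbind, basis[seq_len(k)])
  }
  raw <- apply(raw, 2L, function(m) {
    m <- m - mean(m); m / sqrt(sum(m^2))
  })
  # symmetric orthogonalisation: W = M (M'M)^(-1/2); stays average-
  # referenced because the column space of M is mean-free
  e <- eigen(crossprod(raw), symmetric = TRUE)
  if (min(e$values) < 1e-10) stop("degenerate raw maps for this montage")
  w <- raw %*% (e$vectors %*% diag(1 / sqrt(e$values), k) %*% t(e$vectors))
  template_set(w, labels = LETTERS[seq_len(k)], level = "group")
}
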