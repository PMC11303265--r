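#' Atomize-and-agglomerate hierarchical clustering of topographies
#'
#' Polarity-invariant AAHC: every map starts as its own cluster; the
#' cluster contributing least to the global explained variance (GEV) is
#' atomized and each orphan map is reassigned to the cluster whose
#' centroid it correlates with most strongly in absolute value. Centroids
#' are the first principal component of member maps -- the
#' polarity-invariant analogue of the mean -- re-centred to zero channel
#' mean and unit norm. Exactly `n - k` atomization rounds are performed.
#'
#' A cluster's GEV contribution is `sum((w_i * |corr(map_i, centroid)|)^2)`
#' over its members, with `w_i` the GFP of map `i` at extraction time
#' (uniform weights when no GFP is supplied).
#'
#' @param maps channels x n matrix of topographies (e.g. GFP-peak maps).
#' @param k number of clusters, `1 <= k <= n`.
#' @param gfp_weights optional nonnegative per-map weights (GFP values);
#'   default uniform.
#' @return A [template_set] (subject level, labels `M1..Mk`) with
#'   attributes `assignment` (cluster index per input map), `gev`
#'   (achieved GEV fraction of the clustering) and `rounds`.
#' @export
aahc_cluster <- function(maps, k, gfp_weights = NULL) {
  maps <- as.matrix(maps)
  n <- ncol(maps)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("need 1 <= k <= number of maps")
  if (is.null(gfp_weights)) gfp_weights <- rep(1, n)
  if (length(gfp_weights) != n || any(gfp_weights < 0))
    stop("gfp_weights must be nonnegative, one per map")
  norm_maps <- .normalize_maps(maps)
  if (anyNA(norm_maps)) stop("zero-variance map cannot be clustered")

  assignment <- seq_len(n)
  centroids <- norm_maps                 # cluster c's centroid in column c
  active <- rep(TRUE, n)
  w2 <- gfp_weights^2
  # members' |corr| with own centroid; contribution_c = sum(w2 * corr^2)
  corr_own <- rep(1, n)
  contribution <- w2
  rounds <- 0L

  cluster_members <- function(c) which(assignment == c)

  update_cluster <- function(c) {
    mem <- cluster_members(c)
    m <- norm_maps[, mem, drop = FALSE]
    if (length(mem) == 1L) {
      ctr <- m[, 1L]
    } else {
      ctr <- svd(m, nu = 1L, nv = 0L)$u[, 1L]
      ctr <- ctr - mean(ctr)
      ctr <- ctr / sqrt(sum(ctr^2))
      if (sum(ctr * m[, 1L]) < 0) ctr <- -ctr   # deterministic sign
    }
    centroids[, c] <<- ctr
    cc <- abs(as.numeric(crossprod(ctr, m)))
    corr_own[mem] <<- cc
    contribution[c] <<- sum(w2[mem] * cc^2)
  }

  while (sum(active) > k) {
    act <- which(active)
    worst <- act[which.min(contribution[act])]
    orphans <- cluster_members(worst)
    active[worst] <- FALSE
    act <- which(active)
    cors <- abs(crossprod(centroids[, act, drop = FALSE],
                          norm_maps[, orphans, drop = FALSE]))
    best <- act[apply(cors, 2L, which.max)]
    assignment[orphans] <- best
    for (c in unique(best)) update_cluster(c)
    rounds <- rounds + 1L
  }

  act <- which(active)
  out_maps <- centroids[, act, drop = FALSE]
  relabel <- match(assignment, act)
  ts <- template_set(out_maps, labels = paste0("M", seq_along(act)),
                     level = "subject")
  attr(ts, "assignment") <- relabel
  attr(ts, "gev") <- sum(contribution[act]) / sum(w2)
  attr(ts, "rounds") <- rounds
  ts
}

#' Second-level (group) template derivation
#'
#' Pools every subject's k individual template maps and runs a second
#' AAHC across them, yielding the group-level templates. When a
#' `reference` template set is supplied (typically the analytic canonical
#' maps rendered on the working montage), the output is canonically
#' labeled via [label_canonical].
#'
#' @param subject_sets list of [template_set]s, one per subject, each
#'   contributing the same number of maps on the same montage.
#' @param k number of group clusters.
#' @param reference optional [template_set] for canonical labeling.
#' @return A [template_set] at group level.
#' @export
group_templates <- function(subject_sets, k, reference = NULL) {
  if (length(subject_sets) < 2L) stop("need at least 2 subjects")
  per <- vapply(subject_sets, function(s) ncol(s$maps), integer(1))
  if (length(unique(per)) != 1L)
    stop("every subject must contribute the same number of maps")
  pooled <- do.call(cbind, lapply(subject_sets, function(s) s$maps))
  ts <- aahc_cluster(pooled, k)
  ts$level <- "group"
  if (!is.null(reference)) ts <- label_canonical(ts, reference)
  ts
}

#' Canonical A-D labeling by optimal assignment
#'
#' One-to-one matching of templates to reference maps maximizing the
#' total absolute spatial correlation, searched over all permutations
#' (k is small); ties are broken in favour of the lexicographically
#' first label assignment. Each output map is reordered to its reference
#' label and sign-oriented to correlate positively with its reference.
#'
#' @param templates a [template_set] to label.
#' @param reference_set a [template_set] of canonical maps on the same
#'   montage, with the target labels.
#' @return the relabeled [template_set].
#' @export
label_canonical <- function(templates, reference_set) {
  k <- ncol(templates$maps)
  if (ncol(reference_set$maps) != k)
    stop("template count mismatch with reference")
  if (nrow(reference_set$maps) != nrow(templates$maps))
    stop("reference maps must live on the working montage")
  # corr[i, j] = |corr(reference i, template j)|
  cors <- abs(stats::cor(reference_set$maps, templates$maps))
  perms <- .permutations(k)
  best <- NULL; best_score <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    score <- sum(cors[cbind(seq_len(k), p)])
    if (score > best_score + 1e-12) { best_score <- score; best <- p }
  }
  maps <- templates$maps[, best, drop = FALSE]
  for (i in seq_len(k)) {
    if (stats::cor(maps[, i], reference_set$maps[, i]) < 0)
      maps[, i] <- -maps[, i]
  }
  out <- template_set(maps, labels = reference_set$labels,
                      level = templates$level)
  attr(out, "match_correlations") <-
    cors[cbind(seq_len(k), best)]
  out
}

# all permutations of 1..k in lexicographic row order
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (first in seq_len(k)) {
    rest <- matrix(setdiff(seq_len(k), first)[sub], nrow(sub), k - 1L)
    out <- rbind(out, cbind(first, rest, deparse.level = 0))
  }
  out
}
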