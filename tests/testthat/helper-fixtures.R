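# Shared fixtures and independent oracles for the suite.

# tiny montage/recording builders ------------------------------------------

fix_montage <- function(n = 16L) make_disk_montage(n)

# recording whose samples are scaled copies of given template columns
fix_template_recording <- function(tset, labels, amps, fs = 500) {
  data <- tset$maps[, labels, drop = FALSE] *
    rep(amps, each = nrow(tset$maps))
  eeg_recording(data, fs, montage(paste0("E", seq_len(nrow(data))),
                                  fix_montage(max(8L, nrow(data)))$positions[
                                    seq_len(nrow(data)), , drop = FALSE]))
}

# noisy copies of reference maps (for clustering recovery tests)
fix_noisy_copies <- function(maps, per, snr = 10, seed = 1) {
  set.seed(seed)
  out <- maps[, rep(seq_len(ncol(maps)), each = per), drop = FALSE]
  noise_sd <- sqrt(mean(out^2)) / snr
  out + matrix(rnorm(length(out), sd = noise_sd), nrow(out))
}

# brute-force oracles -------------------------------------------------------

# GEV of a fixed partition using first-PC centroids (independent of the
# aahc implementation's incremental bookkeeping)
oracle_partition_gev <- function(maps, assignment, weights = NULL) {
  maps <- apply(maps, 2L, function(m) {
    m <- m - mean(m); m / sqrt(sum(m^2))
  })
  if (is.null(weights)) weights <- rep(1, ncol(maps))
  tot <- 0
  for (cl in unique(assignment)) {
    mem <- which(assignment == cl)
    sub <- maps[, mem, drop = FALSE]
    ctr <- if (length(mem) == 1L) sub[, 1L] else svd(sub, nu = 1L)$u[, 1L]
    ctr <- ctr - mean(ctr); ctr <- ctr / sqrt(sum(ctr^2))
    tot <- tot + sum((weights[mem] * abs(crossprod(ctr, sub)))^2)
  }
  tot / sum(weights^2)
}

# all set partitions of n items into exactly k blocks (restricted growth)
oracle_partitions <- function(n, k) {
  out <- list()
  recur <- function(a, maxu) {
    i <- length(a) + 1L
    if (i > n) {
      if (maxu == k) out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (b in seq_len(min(maxu + 1L, k)))
      recur(c(a, b), max(maxu, b))
  }
  recur(integer(0), 0L)
  out
}

# exhaustive best-GEV partition over all assignments into k blocks
oracle_best_partition <- function(maps, k, weights = NULL) {
  parts <- oracle_partitions(ncol(maps), k)
  gevs <- vapply(parts, function(p)
    oracle_partition_gev(maps, p, weights), numeric(1))
  list(assignment = parts[[which.max(gevs)]], gev = max(gevs))
}

# textbook sums-of-squares oracle for the mixed Group x Class design
oracle_mixed_anova <- function(values, groups) {
  groups <- factor(groups)
  n <- nrow(values); k <- ncol(values); g <- nlevels(groups)
  gm <- mean(values)
  si <- rowMeans(values)
  mg <- tapply(si, groups, mean)
  ng <- tabulate(groups)
  mc <- colMeans(values)
  mgc <- apply(values, 2L, function(col) tapply(col, groups, mean))
  ss_group <- k * sum(ng * (mg - gm)^2)
  ss_subj <- k * sum((si - gm)^2) - ss_group
  ss_class <- n * sum((mc - gm)^2)
  ss_int <- sum(ng * (mgc - matrix(mg, g, k) -
                        matrix(mc, g, k, byrow = TRUE) + gm)^2)
  ss_err <- sum((values - si)^2) - (ss_class + ss_int) # balanced identity
  ms <- function(ss, df) ss / df
  list(F_group = ms(ss_group, g - 1) / ms(ss_subj, n - g),
       F_class = ms(ss_class, k - 1) / ms(ss_err, (n - g) * (k - 1)),
       F_int = ms(ss_int, (g - 1) * (k - 1)) / ms(ss_err, (n - g) * (k - 1)))
}

# separable two-class feature set for classifier contracts
fix_separable_table <- function(n_per = 12L, p_noise = 2L, gap = 6,
                                seed = 1) {
  set.seed(seed)
  x <- cbind(sig = c(rnorm(n_per, 0), rnorm(n_per, gap)),
             matrix(rnorm(2 * n_per * p_noise), 2 * n_per, p_noise))
  colnames(x) <- c("sig", paste0("noise", seq_len(p_noise)))
  feature_table(x, rep(c("HC", "MD"), each = n_per))
}

# features-only cohort wrapped for the classifier
fix_cohort_table <- function(n_md = 32L, n_hc = 29L, seed = 1) {
  co <- suppressWarnings(
    simulate_cohort(cohort_spec(n_per_group = c(MD = n_md, HC = n_hc),
                                seed = seed)))
  x <- as.matrix(co$features[, -(1:2)])
  demo <- cbind(age = co$clinical$age_y,
                sex = as.numeric(co$clinical$sex == "F"),
                edu = co$clinical$education_y)
  feature_table(cbind(x, demo), co$features$group)
}
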