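#' Reference group-level microstate parameters
#'
#' The generating targets of the default synthetic cohort: per-class mean
#' duration (ms), occurrence (/s) and the 12 joint transition
#' probabilities, with between-subject SDs, for a patient (MD) and a
#' control (HC) group. Values emulate group-level statistics reported in
#' the clinical literature on Meniere's disease: patients show
#' higher class-C occurrence/coverage, fewer A-B and A-D transitions and
#' more A-to-C and B-to-C transitions.
#'
#' @return nested list with `duration`, `occurrence`, `transitions`
#'   (each mean/sd per group) and the transition pair names.
#' @export
microstate_reference_params <- function() {
  pairs <- c("AB", "AC", "AD", "BA", "BC", "BD",
             "CA", "CB", "CD", "DA", "DB", "DC")
  list(
    classes = c("A", "B", "C", "D"),
    pairs = pairs,
    duration = list(
      MD = list(mean = c(63.56, 59.71, 70.77, 69.17),
                sd = c(13.08, 9.29, 25.48, 30.98)),
      HC = list(mean = c(68.39, 64.39, 61.64, 63.70),
                sd = c(12.69, 10.64, 15.76, 10.36))),
    occurrence = list(
      MD = list(mean = c(3.79, 3.52, 4.08, 3.81),
                sd = c(0.81, 1.07, 1.04, 1.44)),
      HC = list(mean = c(4.31, 4.07, 2.78, 4.12),
                sd = c(0.78, 0.99, 1.20, 0.89))),
    transitions = list(
      MD = list(mean = c(0.06, 0.10, 0.08, 0.06, 0.08, 0.08,
                         0.10, 0.07, 0.08, 0.08, 0.08, 0.08),
                sd = c(0.02, 0.07, 0.03, 0.02, 0.03, 0.05,
                       0.07, 0.03, 0.03, 0.03, 0.05, 0.03)),
      HC = list(mean = c(0.11, 0.06, 0.10, 0.11, 0.05, 0.10,
                         0.06, 0.06, 0.06, 0.10, 0.09, 0.06),
                sd = c(0.04, 0.03, 0.03, 0.04, 0.03, 0.03,
                       0.03, 0.03, 0.04, 0.03, 0.03, 0.04))))
}

#' Default clinical model of the synthetic cohort
#'
#' Group-wise distributions for demographics, questionnaires (drawn as
#' truncated normals at the published medians/IQRs; item-level structure
#' is out of scope), audiometry and posturography, plus the default
#' couplings linking clinical scores to microstate features: vertigo
#' symptom load anti-correlates with A-B transitions, equilibrium scores
#' in the somatosensory-challenge conditions and ankle-strategy scores
#' correlate positively with class-C dynamics. Pure-tone average is
#' deliberately uncoupled (the literature reports no association).
#'
#' @return list of per-group clinical parameters and a `couplings`
#'   data.frame (`var`, `feature`, `rho`).
#' @export
default_clinical_model <- function() {
  list(
    MD = list(age = c(54.75, 11.93), female_prob = 23 / 32,
              education = c(12, 4.45), vss = c(23.5, 18.5),
              phq9 = c(6, 6.3), gad7 = c(4.5, 5.2),
              pta = c(45.94, 25.29), history = c(3.96, 6.69),
              es_mean = c(93, 90, 88, 74, 52, 50),
              es_sd = c(3, 3, 4, 10, 14, 14),
              sc_mean = c(85, 85, 80, 70, 62, 58),
              sc_sd = c(6, 6, 8, 9, 10, 10),
              ability_sd = 6),
    HC = list(age = c(56.69, 14.52), female_prob = 22 / 29,
              education = c(12, 2.2), vss = c(2, 4.8),
              phq9 = c(2, 4.8), gad7 = c(0, 1.5),
              pta = c(27.14, 17.58), history = c(0, 0),
              es_mean = c(94, 91, 89, 76, 54, 51),
              es_sd = c(3, 3, 4, 10, 14, 14),
              sc_mean = c(86, 86, 82, 73, 65, 61),
              sc_sd = c(6, 6, 8, 9, 10, 10),
              ability_sd = 6),
    couplings = data.frame(
      var = c("vss", "es4", "es6", "sc4", "sc6"),
      feature = c("t_AB", "t_AC", "t_AC", "occ_C", "occ_C"),
      rho = c(-0.45, 0.39, 0.36, 0.40, 0.40),
      stringsAsFactors = FALSE)
  )
}

#' Build a cohort specification
#'
#' Defines the generating conditions of a two-group synthetic cohort.
#' By default both groups take their parameters from
#' [microstate_reference_params]; supplying `group_effect` instead
#' derives the patient group from the control group by per-class
#' occurrence multipliers and per-pair transition multipliers (all 1
#' makes the groups statistically exchangeable, the null construction).
#'
#' @param n_per_group integer vector `c(MD, HC)` (each >= 3).
#' @param group_effect optional list with `occurrence` (4 multipliers)
#'   and `transitions` (12 multipliers) applied to the control means to
#'   form the patient means; `NULL` uses the reference tables.
#' @param clinical_model a list shaped like [default_clinical_model].
#' @param seed integer seed stored with the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(MD = 32L, HC = 29L),
                        group_effect = NULL,
                        clinical_model = default_clinical_model(),
                        seed = 1L) {
  if (any(n_per_group < 3L)) stop("n_per_group must be >= 3")
  params <- microstate_reference_params()
  if (!is.null(group_effect)) {
    stopifnot(length(group_effect$occurrence) == 4L,
              length(group_effect$transitions) == 12L)
    params$occurrence$MD$mean <-
      params$occurrence$HC$mean * group_effect$occurrence
    params$occurrence$MD$sd <- params$occurrence$HC$sd
    params$transitions$MD$mean <-
      params$transitions$HC$mean * group_effect$transitions
    params$transitions$MD$mean <-
      params$transitions$MD$mean / sum(params$transitions$MD$mean)
    params$transitions$MD$sd <- params$transitions$HC$sd
    params$duration$MD <- params$duration$HC
  }
  if (any(abs(clinical_model$couplings$rho) > 1))
    stop("coupling coefficients must lie in [-1, 1]")
  structure(list(n_per_group = n_per_group, params = params,
                 clinical_model = clinical_model,
                 group_effect = group_effect, seed = seed),
            class = "cohort_spec")
}

#' Null cohort specification
#'
#' Both groups share the control group's microstate parameters and
#' clinical model and all couplings are zeroed: the two groups are
#' statistically exchangeable.
#'
#' @inheritParams cohort_spec
#' @return a `cohort_spec`.
#' @export
null_cohort_spec <- function(n_per_group = c(MD = 32L, HC = 29L),
                             seed = 1L) {
  cm <- default_clinical_model()
  cm$MD <- cm$HC
  cm$couplings$rho <- 0
  cohort_spec(n_per_group,
              group_effect = list(occurrence = rep(1, 4),
                                  transitions = rep(1, 12)),
              clinical_model = cm, seed = seed)
}

# truncated normal by rejection (clamped after 200 tries)
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop("sd must be >= 0")
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 200L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
    tries <- tries + 1L
  }
  pmin(pmax(out, lo), hi)
}

# couple a clinical draw to a feature: keep mean/sd, impose correlation
.couple <- function(base, mu, sigma, feature_values, rho) {
  if (rho == 0 || sigma == 0 || stats::sd(feature_values) == 0) return(base)
  zf <- scale(feature_values)[, 1L]
  zb <- (base - mu) / sigma
  mu + sigma * (rho * zf + sqrt(1 - rho^2) * zb)
}

#' Simulate a two-group cohort
#'
#' Draws per-subject generating microstate parameters (per-class duration
#' and occurrence, 12 joint transition probabilities) from the group
#' models, derives coverage as `occurrence x duration / 10` renormalized
#' to 100%, then draws the clinical table with the configured couplings
#' imposed on the matching features.
#'
#' Modes: `"features"` (fast; the drawn generating parameters are emitted
#' directly as the per-subject feature table) and `"eeg"` (a semi-Markov
#' recording is synthesized per subject from the drawn durations and the
#' conditional transition matrix; features must then be recovered by the
#' analysis pipeline).
#'
#' @param spec a [cohort_spec].
#' @param mode `"features"` or `"eeg"`.
#' @param seed overrides `spec$seed` when given.
#' @param eeg_duration_s,eeg_channels,eeg_fs,eeg_snr synthesis settings
#'   for `"eeg"` mode.
#' @return list with `features` (data.frame, NULL in eeg mode),
#'   `clinical` (data.frame), `recordings` (eeg mode: list of
#'   `simulate_recording`-style bundles), and `spec`.
#' @export
simulate_cohort <- function(spec, mode = c("features", "eeg"), seed = NULL,
                            eeg_duration_s = 60, eeg_channels = 32L,
                            eeg_fs = 500, eeg_snr = 4) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  pr <- spec$params
  cmod <- spec$clinical_model
  groups <- rep(c("MD", "HC"), spec$n_per_group)
  n <- length(groups)
  pairs <- pr$pairs

  dur <- occ <- matrix(NA_real_, n, 4,
                       dimnames = list(NULL, pr$classes))
  trans <- matrix(NA_real_, n, 12, dimnames = list(NULL, pairs))
  for (g in c("MD", "HC")) {
    idx <- which(groups == g)
    for (c_i in 1:4) {
      dur[idx, c_i] <- .rtnorm(length(idx), pr$duration[[g]]$mean[c_i],
                               pr$duration[[g]]$sd[c_i], lo = 20)
      occ[idx, c_i] <- .rtnorm(length(idx), pr$occurrence[[g]]$mean[c_i],
                               pr$occurrence[[g]]$sd[c_i], lo = 0.2)
    }
    for (p_i in 1:12)
      trans[idx, p_i] <- .rtnorm(length(idx), pr$transitions[[g]]$mean[p_i],
                                 pr$transitions[[g]]$sd[p_i], lo = 0.005)
  }
  trans <- trans / rowSums(trans)
  cov_raw <- occ * dur / 10
  cov <- cov_raw / rowSums(cov_raw) * 100

  features <- data.frame(
    stats::setNames(as.data.frame(dur), paste0("dur_", pr$classes)),
    stats::setNames(as.data.frame(cov), paste0("cov_", pr$classes)),
    stats::setNames(as.data.frame(occ), paste0("occ_", pr$classes)),
    stats::setNames(as.data.frame(trans), paste0("t_", pairs)))

  clinical <- .simulate_clinical(groups, cmod, features)
  clinical <- cbind(subject_id = sprintf("S%03d", seq_len(n)),
                    group = groups, clinical, stringsAsFactors = FALSE)

  recordings <- NULL
  if (mode == "eeg") {
    recordings <- vector("list", n)
    for (i in seq_len(n)) {
      m <- conditional_transition_matrix(trans[i, ], k = 4L)
      recordings[[i]] <- simulate_recording(
        n_channels = eeg_channels, k = 4L, transition_matrix = unname(m),
        mean_durations_ms = dur[i, ], fs_hz = eeg_fs,
        duration_s = eeg_duration_s, snr = eeg_snr,
        seed = seed + 1000L + i)
    }
  }

  list(features = if (mode == "features")
         cbind(subject_id = clinical$subject_id, group = groups, features,
               stringsAsFactors = FALSE) else NULL,
       clinical = clinical, recordings = recordings, spec = spec,
       generating = list(duration = dur, occurrence = occ,
                         transitions = trans))
}

.simulate_clinical <- function(groups, cmod, features) {
  n <- length(groups)
  out <- data.frame(row.names = seq_len(n))
  draw <- function(field, lo = -Inf, hi = Inf) {
    v <- numeric(n)
    for (g in c("MD", "HC")) {
      idx <- which(groups == g)
      p <- cmod[[g]][[field]]
      v[idx] <- .rtnorm(length(idx), p[1L], p[2L], lo, hi)
    }
    v
  }
  out$age_y <- round(draw("age", 18, 90))
  out$sex <- ifelse(stats::runif(n) <
                      ifelse(groups == "MD", cmod$MD$female_prob,
                             cmod$HC$female_prob), "F", "M")
  out$education_y <- round(draw("education", 0, 22))
  out$vss_total <- draw("vss", 0, 60)
  out$phq9 <- draw("phq9", 0, 27)
  out$gad7 <- draw("gad7", 0, 21)
  pta_target <- draw("pta", 0, 110)
  out$history_y <- ifelse(groups == "MD",
                          .rtnorm(n, cmod$MD$history[1L],
                                  cmod$MD$history[2L], 0, 40), 0)

  es <- sc <- matrix(NA_real_, n, 6)
  for (g in c("MD", "HC")) {
    idx <- which(groups == g)
    p <- cmod[[g]]
    ability <- stats::rnorm(length(idx), 0, p$ability_sd)
    for (j in 1:6) {
      es[idx, j] <- p$es_mean[j] + ability +
        stats::rnorm(length(idx), 0, p$es_sd[j])
      sc[idx, j] <- .rtnorm(length(idx), p$sc_mean[j], p$sc_sd[j], 0, 100)
    }
  }

  # impose the configured clinical-feature couplings group-wise
  cpl <- cmod$couplings
  get_target <- function(var) {
    if (var %in% c("vss")) return(list(get = function() out$vss_total,
                                       set = function(v) out$vss_total <<- v,
                                       lo = 0, hi = 60, field = "vss"))
    if (grepl("^es[1-6]$", var)) {
      j <- as.integer(substring(var, 3L))
      return(list(get = function() es[, j],
                  set = function(v) es[, j] <<- v,
                  lo = 0, hi = 100, field = "es"))
    }
    if (grepl("^sc[1-6]$", var)) {
      j <- as.integer(substring(var, 3L))
      return(list(get = function() sc[, j],
                  set = function(v) sc[, j] <<- v,
                  lo = 0, hi = 100, field = "sc"))
    }
    NULL
  }
  for (r in seq_len(nrow(cpl))) {
    tgt <- get_target(cpl$var[r])
    if (is.null(tgt) || !cpl$feature[r] %in% names(features)) next
    v <- tgt$get()
    for (g in c("MD", "HC")) {
      idx <- which(groups == g)
      p <- cmod[[g]]
      musd <- switch(tgt$field,
                     vss = p$vss,
                     es = c(p$es_mean[as.integer(substring(cpl$var[r], 3L))],
                            sqrt(p$es_sd[as.integer(
                              substring(cpl$var[r], 3L))]^2 + p$ability_sd^2)),
                     sc = c(p$sc_mean[as.integer(substring(cpl$var[r], 3L))],
                            p$sc_sd[as.integer(substring(cpl$var[r], 3L))]))
      v[idx] <- .couple(v[idx], musd[1L], musd[2L],
                        features[idx, cpl$feature[r]], cpl$rho[r])
    }
    tgt$set(pmin(pmax(v, tgt$lo), tgt$hi))
  }

  es <- pmin(pmax(es, 0), 100)
  colnames(es) <- paste0("es", 1:6)
  colnames(sc) <- paste0("sc", 1:6)
  out <- cbind(out, es, sc)

  # vertigo subscales split off the (possibly coupled) total
  frac <- pmin(pmax(stats::rnorm(n, 0.6, 0.1), 0.3), 0.9)
  out$vss_ver <- round(out$vss_total * frac, 1)
  out$vss_aa <- round(out$vss_total - out$vss_ver, 1)
  out$vss_total <- round(out$vss_total, 1)
  out$phq9 <- round(out$phq9)
  out$gad7 <- round(out$gad7)

  # audiogram: per-frequency jitter around the target, PTA recomputed
  freqs <- c("0.25", "0.5", "1", "2", "4", "8")
  thr <- vapply(seq_len(n), function(i)
    pmax(pta_target[i] + stats::rnorm(6, 0, 4), -5), numeric(6))
  thr <- round(t(thr) / 5) * 5            # audiometric 5-dB steps
  colnames(thr) <- paste0("thr_", freqs, "k")
  out <- cbind(out, thr)
  out$pta_db <- vapply(seq_len(n), function(i)
    compute_pta(stats::setNames(thr[i, ], freqs)), numeric(1))
  out$stage <- vapply(out$pta_db,
                      function(p) as.character(stage_from_pta(p)),
                      character(1))

  ratios <- t(vapply(seq_len(n), function(i)
    unlist(cdp_ratios(es[i, ])), numeric(4)))
  out$ecs <- vapply(seq_len(n), function(i)
    composite_equilibrium(es[i, ]), numeric(1))
  out$som <- ratios[, 1L]; out$vis <- ratios[, 2L]
  out$vest <- ratios[, 3L]; out$pref <- ratios[, 4L]
  out
}
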