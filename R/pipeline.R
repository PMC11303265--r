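#' Subject-level microstate analysis
#'
#' The per-subject pipeline on an already conditioned recording
#' (average-referenced, analysis band, segmented): GFP, GFP-peak
#' extraction, AAHC clustering of the peak topographies into k subject
#' templates, backfitting, global explained variance and the temporal
#' feature bundle. Templates are canonically labeled against `reference`
#' (defaults to the analytic canonical maps on the recording's montage).
#'
#' Backfitting uses the pipeline configuration's labeling mode and
#' minimum-duration smoothing (defaults: per-sample argmax with 12-ms
#' smoothing; see the methods vignette for the rationale and
#' sensitivity modes).
#'
#' @param rec a preprocessed [eeg_recording].
#' @param k number of classes (default from config).
#' @param config list from [default_pipeline_config].
#' @param reference optional [template_set] for canonical labeling; NULL
#'   builds the analytic maps, NA skips labeling.
#' @param templates optional: backfit these instead of clustering (used
#'   when group templates are fitted back into individual data).
#' @return list with `templates`, `segmentation`, `gev`, `features`,
#'   `gfp_peaks` (indices), `n_peaks`.
#' @export
analyze_recording <- function(rec, k = NULL,
                              config = default_pipeline_config(),
                              reference = NULL, templates = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(k)) k <- config$k
  if (is.null(rec$segments)) rec <- segment_recording(rec, config$segment_s)
  rec <- rereference_average(rec)
  gfp <- compute_gfp(rec)
  peaks <- find_gfp_peaks(gfp, rec$fs_hz,
                          min_separation_ms = config$min_peak_separation_ms,
                          segments = rec$segments)
  if (is.null(templates)) {
    if (length(peaks) < k) stop("too few GFP peaks to cluster")
    templates <- aahc_cluster(rec$data[, peaks, drop = FALSE], k,
                              gfp_weights = gfp[peaks])
    if (is.null(reference))
      reference <- make_canonical_templates(rec$montage, k)
    if (inherits(reference, "template_set"))
      templates <- label_canonical(templates, reference)
  }
  seg <- backfit(rec, templates,
                 mode = if (is.null(config$backfit_mode)) "sample"
                        else config$backfit_mode,
                 smooth_min_ms = config$smooth_min_ms,
                 min_peak_separation_ms = config$min_peak_separation_ms)
  gev <- compute_gev(rec, seg, templates)
  list(templates = templates, segmentation = seg, gev = gev,
       features = microstate_features(seg), gfp_peaks = peaks,
       n_peaks = length(peaks))
}

#' Group-level microstate analysis over a cohort of recordings
#'
#' Stage one: subject-level AAHC templates per recording. Stage two:
#' second AAHC across all subjects' templates, canonically labeled.
#' Stage three: the group templates are backfitted into each subject's
#' data and per-subject features extracted.
#'
#' @param recordings list of preprocessed [eeg_recording]s.
#' @param k classes (default from config).
#' @param config pipeline configuration.
#' @return list with `group_templates`, `subject_templates`, `results`
#'   (per-subject [analyze_recording] output under the group templates)
#'   and a `features` data.frame (one [feature_row] per subject).
#' @export
analyze_cohort_recordings <- function(recordings, k = NULL,
                                      config = default_pipeline_config()) {
  if (length(recordings) < 2L) stop("need >= 2 subjects for group stages")
  if (is.null(k)) k <- config$k
  subj <- lapply(recordings, function(r)
    analyze_recording(r, k, config, reference = NA)$templates)
  reference <- make_canonical_templates(recordings[[1L]]$montage, k)
  grp <- group_templates(subj, k, reference = reference)
  results <- lapply(recordings, function(r)
    analyze_recording(r, k, config, templates = grp))
  features <- do.call(rbind, lapply(results, function(x)
    feature_row(x$features)))
  list(group_templates = grp, subject_templates = subj,
       results = results, features = as.data.frame(features))
}

#' Group statistics report over a cohort feature table
#'
#' The statistical layer applied to a simulated (or recovered) cohort:
#' demographic/clinical comparisons with the normality gate, mixed
#' Group x Class ANOVAs with Bonferroni post hoc tests for each temporal
#' parameter family, transition-wise post hoc tests, and Spearman
#' correlations between the configured clinical scores and microstate
#' features within the patient group.
#'
#' @param features data.frame from `simulate_cohort(...)$features` (or
#'   recovered equivalents) with a `group` column.
#' @param clinical matching clinical data.frame.
#' @return list of `demographics` (group_comparison list), `anova`
#'   (per family), `transitions` (post hoc table), `correlations`
#'   (Spearman table within MD).
#' @export
cohort_group_stats <- function(features, clinical) {
  grp <- factor(features$group, levels = c("MD", "HC"))
  fam <- function(prefix) as.matrix(
    features[, paste0(prefix, c("A", "B", "C", "D"))])
  demo <- list(
    age = compare_groups(clinical$age_y[grp == "MD"],
                         clinical$age_y[grp == "HC"], variable = "age"),
    sex = compare_groups(table(clinical$group, clinical$sex),
                         kind = "categorical", variable = "sex"),
    vss = compare_groups(clinical$vss_total[grp == "MD"],
                         clinical$vss_total[grp == "HC"], variable = "VSS"),
    ecs = compare_groups(clinical$ecs[grp == "MD"],
                         clinical$ecs[grp == "HC"], variable = "ECs"))
  anova <- list(
    duration = rm_anova_group_class(fam("dur_"), grp),
    coverage = rm_anova_group_class(fam("cov_"), grp),
    occurrence = rm_anova_group_class(fam("occ_"), grp))
  tcols <- grep("^t_", names(features), value = TRUE)
  raw <- vapply(tcols, function(cn)
    stats::t.test(features[grp == "MD", cn], features[grp == "HC", cn],
                  var.equal = TRUE)$p.value, numeric(1))
  dir <- vapply(tcols, function(cn)
    mean(features[grp == "MD", cn]) - mean(features[grp == "HC", cn]),
    numeric(1))
  trans <- cbind(pair = sub("^t_", "", tcols),
                 bonferroni_posthoc(raw, m = length(raw)),
                 md_minus_hc = dir)
  md <- which(grp == "MD")
  cor_pairs <- list(c("vss_total", "t_AB"), c("vss_ver", "t_AB"),
                    c("es4", "t_AC"), c("es6", "t_AC"),
                    c("sc4", "occ_C"), c("sc6", "occ_C"),
                    c("pta_db", "occ_C"))
  correlations <- do.call(rbind, lapply(cor_pairs, function(p) {
    s <- spearman_cor(clinical[md, p[1L]], features[md, p[2L]])
    data.frame(clinical = p[1L], feature = p[2L], rho = s$rho, p = s$p)
  }))
  list(demographics = demo, anova = anova, transitions = trans,
       correlations = correlations)
}

#' Ground-truth recovery experiment
#'
#' Synthesizes one long recording under known conditions, runs the full
#' subject-level pipeline (segment, GFP peaks, AAHC, canonical labeling,
#' backfit, features) and measures recovery: mean absolute correlation
#' between estimated and generating templates, GFP-peak label agreement,
#' per-class duration and occurrence errors against the ground-truth
#' label sequence, maximal joint-transition error, and GEV.
#'
#' @param duration_s recording length (default 600).
#' @param n_channels montage size (default 32).
#' @param fs_hz sampling rate (default 500).
#' @param snr linear SNR (default 4).
#' @param seed integer seed.
#' @param config pipeline configuration.
#' @return list of recovery measures (see Details) plus the underlying
#'   objects.
#' @export
recovery_experiment <- function(duration_s = 600, n_channels = 32L,
                                fs_hz = 500, snr = 4, seed = 1L,
                                config = default_pipeline_config()) {
  sim <- simulate_recording(n_channels = n_channels, k = 4L,
                            mean_durations_ms = c(65, 62, 66, 66),
                            fs_hz = fs_hz, duration_s = duration_s,
                            snr = snr, seed = seed)
  rec <- segment_recording(sim$recording, config$segment_s)
  res <- analyze_recording(rec, 4L, config)
  truth <- sim$truth

  tcorr <- attr(label_canonical(res$templates, truth$templates),
                "match_correlations")
  peaks <- res$gfp_peaks
  agree <- mean(res$segmentation$labels[peaks] ==
                  truth$state_sequence[peaks])

  true_seg <- structure(list(labels = truth$state_sequence,
                             segments = rec$segments, fs_hz = fs_hz,
                             template_labels = LETTERS[1:4],
                             gfp = res$segmentation$gfp),
                        class = "segmentation")
  truth_feat <- microstate_features(true_seg)
  est <- res$features
  list(
    template_corr = tcorr,
    mean_template_corr = mean(tcorr),
    peak_agreement = agree,
    duration_error_ms = est$duration_ms - truth_feat$duration_ms,
    occurrence_error_hz = est$occurrence_hz - truth_feat$occurrence_hz,
    coverage_error_pct = est$coverage_pct - truth_feat$coverage_pct,
    transition_error = as.numeric(est$transitions) -
      as.numeric(truth_feat$transitions),
    gev_total = res$gev$total,
    estimated = est, truth_features = truth_feat, analysis = res,
    truth = truth
  )
}
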