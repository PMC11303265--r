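#' Pure-tone average
#'
#' Simple arithmetic mean of the 0.5, 1 and 2 kHz pure-tone thresholds.
#'
#' @param thresholds_db named numeric vector of thresholds in dB HL;
#'   names are frequencies in kHz (`"0.5"`, `"1"`, `"2"` required; other
#'   frequencies may be present and are ignored).
#' @return PTA in dB HL.
#' @export
compute_pta <- function(thresholds_db) {
  need <- c("0.5", "1", "2")
  missing_f <- need[!need %in% names(thresholds_db)]
  if (length(missing_f) > 0L)
    stop("missing threshold at ", paste(missing_f, collapse = ", "), " kHz")
  mean(thresholds_db[need])
}

#' Hearing stage from PTA
#'
#' Stage I: PTA <= 25 dB HL; II: 26-40; III: 41-70; IV: > 70. The printed
#' bands are integers with a gap between 25 and 26, so fractional PTA is
#' rounded half-up to the nearest integer before staging. Negative PTA is
#' unusual but possible and accepted with a warning.
#'
#' @param pta_db finite PTA in dB HL.
#' @return stage as an ordered factor `I < II < III < IV`.
#' @export
stage_from_pta <- function(pta_db) {
  if (!is.finite(pta_db)) stop("PTA must be finite")
  if (pta_db < 0) warning("negative PTA accepted (unusual)")
  p <- floor(pta_db + 0.5)   # round half-up
  stage <- if (p <= 25) "I" else if (p <= 40) "II" else if (p <= 70) "III" else "IV"
  factor(stage, levels = c("I", "II", "III", "IV"), ordered = TRUE)
}

#' Sensory-analysis ratios of the sensory organization test
#'
#' SOM = ES2/ES1, VIS = ES4/ES1, VEST = ES5/ES1,
#' PREF = (ES3 + ES6)/(ES2 + ES5). A zero denominator (the subject fell
#' on all reference trials) yields NA with a warning.
#'
#' @param es numeric vector of the six equilibrium scores ES1..ES6
#'   (each 0-100).
#' @return named list `som`, `vis`, `vest`, `pref`.
#' @export
cdp_ratios <- function(es) {
  if (length(es) != 6L) stop("need the six equilibrium scores ES1..ES6")
  som <- vis <- vest <- pref <- NA_real_
  if (es[1L] > 0) {
    som <- es[2L] / es[1L]; vis <- es[4L] / es[1L]; vest <- es[5L] / es[1L]
  } else warning("ES1 = 0: SOM/VIS/VEST undefined")
  if (es[2L] + es[5L] > 0) pref <- (es[3L] + es[6L]) / (es[2L] + es[5L])
  else warning("ES2 + ES5 = 0: PREF undefined")
  list(som = som, vis = vis, vest = vest, pref = pref)
}

#' Composite equilibrium score
#'
#' Weighted mean of the six condition equilibrium scores. The default
#' weights (1, 1, 3, 3, 3, 3)/14 follow the standard sensory organization
#' test protocol, where conditions 3-6 contribute three trials each;
#' alternative weights are configurable.
#'
#' @param es numeric vector ES1..ES6, no missing values.
#' @param weights nonnegative weights, default `c(1, 1, 3, 3, 3, 3)`.
#' @return composite score (same 0-100 scale as the inputs).
#' @export
composite_equilibrium <- function(es, weights = c(1, 1, 3, 3, 3, 3)) {
  if (length(es) != 6L || anyNA(es)) stop("need all six equilibrium scores")
  if (length(weights) != 6L || any(weights < 0)) stop("invalid weights")
  sum(es * weights) / sum(weights)
}
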