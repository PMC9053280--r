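#' Configuration for a synthetic SESI-HRMS breath cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults emulate
#' the paediatric training-set design: ~75 measurements (25 subjects, 3 visits),
#' slightly over half of them on valproic acid (VPA), 5-6 replicate exhalations
#' per measurement in scan range m/z 100-400, 11 drug-related features from 4
#' molecules, endogenous features tied to toy pathways (some upregulated under
#' side effects, some downregulated in non-responders), plus non-breath
#' nuisance ions and multiplicative batch effects.
#'
#' @param n_subjects Number of subjects.
#' @param visits_per_subject Measurements (visits) per subject.
#' @param frac_vpa Proportion of subjects (hence, approximately, measurements)
#'   receiving VPA. Non-takers are programmed at level 0 mg/L.
#' @param n_exhalations Range (length-2 integer) of replicate exhalations per
#'   measurement; each measurement draws uniformly from this range.
#' @param scan_hz Scan rate (full scans per second).
#' @param n_drug_features Number of drug-related mass-spectral features; the
#'   default 11 is spread over 4 molecules (3-heptanone, 4-OH-gamma-lactone,
#'   heptanedione, VPA itself) via protonated, sodiated and 13C-isotope ions.
#' @param n_endogenous_features Number of breath-correlated endogenous features.
#'   As many as possible are mapped to toy-pathway compounds so that
#'   accurate-mass annotation can recover them.
#' @param n_nuisance_features Number of non-breath-correlated (white-noise)
#'   features.
#' @param effect_size_side_effects Log2-scale shift applied to features of the
#'   side-effect-affected pathways in measurements with side effects (> 0: up).
#' @param effect_size_nonresponse Log2-scale shift applied to features of the
#'   response-affected pathways in non-responder measurements (< 0: down).
#' @param noise_cv Coefficient of variation of the multiplicative measurement
#'   noise (per exhalation and per scan). 0 gives a noise-free cohort.
#' @param n_batches Number of acquisition batches (measurements are assigned in
#'   contiguous blocks, mimicking acquisition dates).
#' @param batch_scale_sd Log-scale SD of the per-(batch, feature) multiplicative
#'   batch factors.
#' @param prev_side_effects,prev_nonresponse,prev_eeg_abnormal Prevalence of
#'   the positive (class II/III) outcome for each clinical axis. Defaults are
#'   the observed study prevalences 23/75, 26/75 and 27/75.
#' @param plateau_range_s,gap_range_s Per-exhalation plateau duration and
#'   inter-exhalation gap, drawn uniformly from these ranges (seconds).
#' @param ramp_s Raised-cosine edge duration of each exhalation pulse (seconds).
#' @param amp_exponent Exponent `b` of the drug-feature amplitude law
#'   `a * free_vpa^b`.
#' @param mz_jitter_ppm Per-scan mass jitter (ppm, 1 SD) applied to centroid
#'   m/z values.
#' @param tic_background Constant non-breath total-ion-current floor (a.u.).
#' @param subject_sd_log2 Per-(subject, feature) biological random effect SD on
#'   the log2 scale for endogenous features.
#' @param seed Integer seed; the generator is deterministic given the config.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [simulate_cohort()], [simulate_feature_matrix()]
#' @export
cohort_config <- function(n_subjects = 25,
                          visits_per_subject = 3,
                          frac_vpa = 50 / 93,
                          n_exhalations = c(5L, 6L),
                          scan_hz = 2,
                          n_drug_features = 11,
                          n_endogenous_features = 40,
                          n_nuisance_features = 60,
                          effect_size_side_effects = log2(1.5),
                          effect_size_nonresponse = -log2(1.5),
                          noise_cv = 0.2,
                          n_batches = 3,
                          batch_scale_sd = 0.3,
                          prev_side_effects = 23 / 75,
                          prev_nonresponse = 26 / 75,
                          prev_eeg_abnormal = 27 / 75,
                          plateau_range_s = c(10, 20),
                          gap_range_s = c(5, 10),
                          ramp_s = 2,
                          amp_exponent = 1,
                          mz_jitter_ppm = 1,
                          tic_background = 3000,
                          subject_sd_log2 = 0.3,
                          seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, visits_per_subject = visits_per_subject,
    frac_vpa = frac_vpa, n_exhalations = n_exhalations, scan_hz = scan_hz,
    n_drug_features = n_drug_features,
    n_endogenous_features = n_endogenous_features,
    n_nuisance_features = n_nuisance_features,
    effect_size_side_effects = effect_size_side_effects,
    effect_size_nonresponse = effect_size_nonresponse,
    noise_cv = noise_cv, n_batches = n_batches,
    batch_scale_sd = batch_scale_sd,
    prev_side_effects = prev_side_effects,
    prev_nonresponse = prev_nonresponse,
    prev_eeg_abnormal = prev_eeg_abnormal,
    plateau_range_s = plateau_range_s, gap_range_s = gap_range_s,
    ramp_s = ramp_s, amp_exponent = amp_exponent,
    mz_jitter_ppm = mz_jitter_ppm, tic_background = tic_background,
    subject_sd_log2 = subject_sd_log2, seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (!all(is.finite(num))) {
    stop("cohort_config rejects non-finite values", call. = FALSE)
  }
  counts <- c("n_subjects", "visits_per_subject", "scan_hz", "n_drug_features",
              "n_batches")
  for (f in counts) {
    if (!is_count(cfg[[f]])) stop(sprintf("`%s` must be a count >= 1", f), call. = FALSE)
  }
  for (f in c("n_endogenous_features", "n_nuisance_features")) {
    if (!(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] == floor(cfg[[f]]))) {
      stop(sprintf("`%s` must be a non-negative integer", f), call. = FALSE)
    }
  }
  if (cfg$frac_vpa < 0 || cfg$frac_vpa > 1) stop("`frac_vpa` must be in [0, 1]", call. = FALSE)
  if (cfg$noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (length(cfg$n_exhalations) != 2 || any(cfg$n_exhalations < 1)) {
    stop("`n_exhalations` must be a range of counts >= 1", call. = FALSE)
  }
  for (p in c("prev_side_effects", "prev_nonresponse", "prev_eeg_abnormal")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("`%s` must be in [0, 1]", p), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects x %d visits (frac on VPA: %.2f), seed %d\n",
              x$n_subjects, x$visits_per_subject, x$frac_vpa, x$seed))
  cat(sprintf("  features: %d drug / %d endogenous / %d nuisance; noise CV %.2f; %d batches\n",
              x$n_drug_features, x$n_endogenous_features, x$n_nuisance_features,
              x$noise_cv, x$n_batches))
  invisible(x)
}
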