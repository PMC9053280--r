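# Synthetic SESI-HRMS cohort generator.
#
# The generator works in two layers. `simulate_design()` draws everything that
# is "true" about a cohort: who takes VPA and at what programmed serum level,
# clinical outcome classes, batch factors, per-feature pulse amplitudes and
# detectability. `simulate_cohort()` then renders scan-level centroided
# spectra from that design, while `simulate_feature_matrix()` renders the
# post-extraction mean-nAUC matrix directly (same amplitude model, skipping
# the scan rendering) for statistically heavy simulations.

#' Raised-cosine exhalation pulse profile
#'
#' The unit pulse train of a measurement: 0 between exhalations, 1 on each
#' plateau, raised-cosine edges of duration `ramp_s`.
#'
#' @param scan_times Numeric vector of times (s).
#' @param schedule Tibble with columns `t_on`, `t_off` (pulse extents incl.
#'   ramps), as stored per measurement in a [synthetic truth][simulate_cohort].
#' @param ramp_s Edge duration (s).
#' @return Numeric vector in [0, 1], one value per scan time.
#' @export
exhalation_profile <- function(scan_times, schedule, ramp_s = 2) {
  p <- numeric(length(scan_times))
  for (k in seq_len(nrow(schedule))) {
    on <- schedule$t_on[k]; off <- schedule$t_off[k]
    inside <- scan_times >= on & scan_times <= off
    t <- scan_times[inside]
    v <- rep(1, length(t))
    up <- t < on + ramp_s
    v[up] <- 0.5 * (1 - cos(pi * (t[up] - on) / ramp_s))
    dn <- t > off - ramp_s
    v[dn] <- 0.5 * (1 - cos(pi * (off - t[dn]) / ramp_s))
    p[inside] <- pmax(p[inside], v)
  }
  p
}

# Exhalation extents at a relative threshold on the pulse profile: the
# interval where the raised-cosine edge exceeds `threshold`.
profile_windows <- function(schedule, ramp_s, threshold = 0.3) {
  dt <- ramp_s * acos(1 - 2 * threshold) / pi
  tibble(start_s = schedule$t_on + dt, end_s = schedule$t_off - dt)
}

# ---- design layer ----------------------------------------------------------

free_fraction <- function(total) 0.07 + 0.08 * total / (total + 100)

simulate_design <- function(config, pathway_db = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  if (is.null(pathway_db)) {
    pathway_db <- make_toy_pathway_db(seed = cfg$seed + 7013L)
  }
  with_seed(cfg$seed, {
    n_subj <- cfg$n_subjects
    n_meas <- n_subj * cfg$visits_per_subject

    # subjects: VPA status, mean serum level, metabolic pathway activities
    n_vpa <- round(cfg$frac_vpa * n_subj)
    on_vpa_subj <- seq_len(n_subj) %in% sample(n_subj, n_vpa)
    subj <- tibble(
      subject_id = sprintf("S%02d", seq_len(n_subj)),
      on_vpa = on_vpa_subj,
      mean_total_vpa = ifelse(on_vpa_subj,
                              pmin(pmax(rlnorm(n_subj, log(70), 0.35), 10), 160), 0),
      beta_ox = rlnorm(n_subj, 0, 0.4),   # 3-heptanone route activity
      omega_ox = rlnorm(n_subj, 0, 0.4)   # 4-OH-gamma-lactone route activity
    )

    # measurements: programmed concentrations, outcomes, batch, schedule
    meas <- tidyr::crossing(subject_id = subj$subject_id,
                            visit = seq_len(cfg$visits_per_subject)) |>
      arrange(.data$subject_id, .data$visit) |>
      left_join(subj, by = "subject_id")
    meas$measurement_id <- sprintf("M%03d", seq_len(n_meas))
    meas$total_vpa_mgL <- ifelse(
      meas$on_vpa,
      pmin(pmax(meas$mean_total_vpa * rlnorm_cv(n_meas, 0.15), 5), 180), 0)
    frac <- free_fraction(meas$total_vpa_mgL) *
      pmax(1 + cfg$noise_cv * 0.3 * rnorm(n_meas), 0.5)
    meas$free_vpa_mgL <- pmin(meas$total_vpa_mgL * frac, meas$total_vpa_mgL)
    pick_class <- function(prev) {
      pos <- runif(n_meas) < prev
      ifelse(pos, sample(c("II", "III"), n_meas, replace = TRUE), "I")
    }
    meas$side_effects_class <- pick_class(cfg$prev_side_effects)
    meas$response_class <- pick_class(cfg$prev_nonresponse)
    meas$eeg_class <- pick_class(cfg$prev_eeg_abnormal)
    meas$batch <- if (cfg$n_batches == 1) "B1" else {
      sprintf("B%d", as.integer(cut(seq_len(n_meas), cfg$n_batches,
                                    labels = FALSE)))
    }
    meas$n_exhalations <- sample(seq(cfg$n_exhalations[1], cfg$n_exhalations[2]),
                                 n_meas, replace = TRUE)
    meas$schedule <- lapply(meas$n_exhalations, function(k) {
      t <- runif(1, 8, 12)
      on <- off <- numeric(k)
      for (i in seq_len(k)) {
        on[i] <- t
        t <- t + 2 * cfg$ramp_s + runif(1, cfg$plateau_range_s[1], cfg$plateau_range_s[2])
        off[i] <- t
        t <- t + runif(1, cfg$gap_range_s[1], cfg$gap_range_s[2])
      }
      tibble(t_on = on, t_off = off)
    })

    # features ---------------------------------------------------------------
    ddefs <- drug_feature_defs()
    idx <- rep_len(seq_len(nrow(ddefs)), cfg$n_drug_features)
    drug <- ddefs[idx, ]
    drug_feat <- tibble(
      kind = "drug", molecule = drug$molecule, ion = drug$ion, mz = drug$mz,
      amp_per_mgL = drug$amp_per_mgL, compound_id = NA_character_,
      pathway_id = NA_character_, affected = "none",
      base_amp = 0, bg_amp = rlnorm(nrow(drug), log(3), 0.3),
      floor = rlnorm(nrow(drug), log(2), 0.2), breath_correlated = TRUE
    )

    endo_cpd <- dplyr::filter(pathway_db$compounds, !.data$is_drug)
    memb <- pathway_members(pathway_db)
    n_endo <- cfg$n_endogenous_features
    n_annot <- min(n_endo, nrow(endo_cpd))
    endo_ids <- endo_cpd$compound_id[seq_len(n_annot)]
    # first pathway membership of each compound, for the affected flag
    first_pw <- memb |> group_by(.data$compound_id) |>
      summarise(pathway_id = dplyr::first(.data$pathway_id), .groups = "drop")
    pw_ids <- pathway_db$pathways$pathway_id
    n_aff <- min(2, length(pw_ids) %/% 2)
    se_pw <- pw_ids[seq_len(n_aff)]
    resp_pw <- pw_ids[n_aff + seq_len(min(n_aff, length(pw_ids) - n_aff))]
    extra <- n_endo - n_annot
    extra_mz <- if (extra > 0) runif(extra, 100, 380) else numeric(0)
    endo_feat <- tibble(
      kind = "endogenous", molecule = NA_character_, ion = "M+H",
      mz = c(endo_cpd$mass[seq_len(n_annot)] + PROTON_MASS, extra_mz + PROTON_MASS),
      amp_per_mgL = 0,
      compound_id = c(endo_ids, rep(NA_character_, extra))
    ) |>
      left_join(first_pw, by = "compound_id") |>
      mutate(
        affected = dplyr::case_when(
          .data$pathway_id %in% se_pw ~ "side_effects_up",
          .data$pathway_id %in% resp_pw ~ "nonresponse_down",
          TRUE ~ "none"
        ),
        base_amp = rlnorm(n_endo, log(80), 0.6),
        bg_amp = 0, floor = rlnorm(n_endo, log(2), 0.2),
        breath_correlated = TRUE
      )

    n_nuis <- cfg$n_nuisance_features
    nuis_feat <- tibble(
      kind = "nuisance", molecule = NA_character_, ion = NA_character_,
      mz = runif(n_nuis, 100.5, 399.5), amp_per_mgL = 0,
      compound_id = NA_character_, pathway_id = NA_character_,
      affected = "none", base_amp = rlnorm(n_nuis, log(40), 0.6),
      bg_amp = 0, floor = 0, breath_correlated = FALSE
    )

    feats <- bind_rows(drug_feat, endo_feat, nuis_feat)
    feats$feature_id <- sprintf("F%03d", seq_len(nrow(feats)))
    # endogenous breath metabolites are mostly consistently detectable (the
    # low tail still exercises the 50%-presence filter); nuisance ions less so
    feats$detect_prob <- dplyr::case_when(
      feats$kind == "drug" ~ NA_real_, # depends on VPA status, handled below
      feats$kind == "endogenous" ~ runif(nrow(feats), 0.75, 1),
      TRUE ~ runif(nrow(feats), 0.4, 1)
    )
    nf <- nrow(feats)

    # batch factors: multiplicative log-normal per (batch, feature)
    batches <- sort(unique(meas$batch))
    bf <- matrix(rlnorm(length(batches) * nf, 0, cfg$batch_scale_sd),
                 nrow = length(batches),
                 dimnames = list(batches, feats$feature_id))

    # subject random effects for endogenous features (log2 scale)
    sre <- matrix(rnorm(n_subj * nf, 0, cfg$subject_sd_log2), nrow = n_subj,
                  dimnames = list(subj$subject_id, feats$feature_id))
    sre[, feats$kind != "endogenous"] <- 0

    # presence draws
    dp <- matrix(rep(feats$detect_prob, each = n_meas), nrow = n_meas)
    drug_cols <- which(feats$kind == "drug")
    dp[, drug_cols] <- ifelse(meas$on_vpa, 0.97, 0.3)
    presence <- matrix(runif(n_meas * nf) < dp, nrow = n_meas,
                       dimnames = list(meas$measurement_id, feats$feature_id))

    # deterministic pulse amplitude per (measurement, feature)
    amp <- matrix(0, n_meas, nf, dimnames = dimnames(presence))
    sidx <- match(meas$subject_id, subj$subject_id)
    bidx <- match(meas$batch, batches)
    route <- ifelse(feats$molecule %in% "3-heptanone", "beta",
                    ifelse(feats$molecule %in% "4-OH-gamma-lactone", "omega", "one"))
    for (j in seq_len(nf)) {
      f <- feats[j, ]
      bfac <- bf[bidx, j]
      if (f$kind == "drug") {
        sfac <- switch(route[j], beta = subj$beta_ox[sidx],
                       omega = subj$omega_ox[sidx], rep(1, n_meas))
        amp[, j] <- f$amp_per_mgL * sfac * meas$free_vpa_mgL^cfg$amp_exponent * bfac
      } else if (f$kind == "endogenous") {
        eff <- rep(0, n_meas)
        if (f$affected == "side_effects_up") {
          eff <- cfg$effect_size_side_effects * (meas$side_effects_class != "I")
        } else if (f$affected == "nonresponse_down") {
          eff <- cfg$effect_size_nonresponse * (meas$response_class != "I")
        }
        amp[, j] <- f$base_amp * 2^(eff + sre[sidx, j]) * bfac
      } else {
        amp[, j] <- f$base_amp * bfac # nuisance mean level (no pulse)
      }
    }
    bg <- matrix(rep(feats$bg_amp, each = n_meas), n_meas, nf,
                 dimnames = dimnames(presence)) *
      bf[bidx, , drop = FALSE]

    list(config = cfg, pathway_db = pathway_db, subjects = subj,
         measurements = select(meas, -"mean_total_vpa"),
         features = select(feats, "feature_id", dplyr::everything()),
         amplitude = amp, pulse_background = bg, presence = presence,
         batch_factors = bf, subject_effects = sre,
         affected_pathways = list(side_effects = se_pw, nonresponse = resp_pw))
  })
}

new_synthetic_truth <- function(design) {
  structure(design, class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d measurements x %d features (%d drug, %d endogenous, %d nuisance)\n",
              nrow(x$measurements), nrow(x$features),
              sum(x$features$kind == "drug"), sum(x$features$kind == "endogenous"),
              sum(x$features$kind == "nuisance")))
  invisible(x)
}

#' Binary outcome from an ordinal clinical class
#'
#' Class I is the reference ("no side effects" / "responder" / "normal EEG");
#' classes II and III together form the positive class.
#'
#' @param class Character vector with values in `c("I", "II", "III")`.
#' @return Logical vector, `TRUE` for class II or III.
#' @export
outcome_positive <- function(class) {
  stopifnot(all(class %in% c("I", "II", "III")))
  class != "I"
}

# ---- scan-level rendering --------------------------------------------------

#' Simulate a synthetic breath cohort with full ground truth
#'
#' Renders scan-level centroided spectra for every measurement of the design
#' described by `config`: each measurement carries 5-6 raised-cosine
#' exhalation pulses in its TIC and in every breath-correlated feature trace;
#' drug-feature pulse amplitudes scale as `a * free_vpa^b` times batch and
#' subject factors and multiplicative log-normal noise; endogenous features
#' shift on the log2 scale with the programmed outcome classes; nuisance
#' features are white noise uncorrelated with the pulses. Deterministic given
#' the config (which includes the seed).
#'
#' @param config A [cohort_config()].
#' @param pathway_db Optional [make_toy_pathway_db()] output; generated from
#'   the config seed when `NULL`.
#' @return A list with `measurements` (list of `raw_measurement` objects) and
#'   `truth` (a `synthetic_truth` carrying the programmed concentrations,
#'   classes, amplitudes, batch factors, presence flags and the pathway
#'   database).
#' @export
simulate_cohort <- function(config, pathway_db = NULL) {
  design <- simulate_design(config, pathway_db)
  cfg <- design$config
  meas <- design$measurements
  feats <- design$features
  nf <- nrow(feats)
  measurements <- with_seed(cfg$seed + 1L, {
    lapply(seq_len(nrow(meas)), function(m) {
      sched <- meas$schedule[[m]]
      t_end <- max(sched$t_off) + 8
      times <- seq(0, t_end, by = 1 / cfg$scan_hz)
      ns <- length(times)
      prof <- exhalation_profile(times, sched, cfg$ramp_s)
      # which exhalation each scan belongs to (0 = none)
      exh_idx <- integer(ns)
      for (k in seq_len(nrow(sched))) {
        exh_idx[times >= sched$t_on[k] & times <= sched$t_off[k]] <- k
      }
      eps <- matrix(rlnorm_cv(nrow(sched) * nf, cfg$noise_cv), nrow(sched), nf)
      pulse_amp <- design$amplitude[m, ] + design$pulse_background[m, ]
      tr <- matrix(0, ns, nf)
      bc <- feats$breath_correlated
      in_exh <- exh_idx > 0
      if (any(bc)) {
        scale_k <- matrix(1, ns, sum(bc))
        scale_k[in_exh, ] <- eps[exh_idx[in_exh], bc, drop = FALSE]
        tr[, bc] <- (rep(feats$floor[bc], each = ns) +
                       outer(prof, pulse_amp[bc]) * scale_k)
      }
      if (any(!bc)) {
        tr[, !bc] <- rep(design$amplitude[m, !bc], each = ns) *
          matrix(rlnorm_cv(ns * sum(!bc), max(cfg$noise_cv, 0)), ns)
      }
      tr <- tr * matrix(rlnorm_cv(ns * nf, cfg$noise_cv * 0.5), ns, nf)
      pres <- design$presence[m, ]
      tr[, !pres] <- 0
      jit <- if (cfg$mz_jitter_ppm > 0) {
        matrix(rnorm(ns * nf, 0, cfg$mz_jitter_ppm * 1e-6), ns, nf)
      } else matrix(0, ns, nf)
      keep <- which(tr > 0, arr.ind = TRUE)
      centroids <- tibble(
        scan = keep[, 1],
        mz = feats$mz[keep[, 2]] * (1 + jit[keep]),
        intensity = tr[keep]
      ) |> arrange(.data$scan, .data$mz)
      tic <- rowSums(tr) + cfg$tic_background * rlnorm_cv(ns, cfg$noise_cv * 0.5)
      new_raw_measurement(
        measurement_id = meas$measurement_id[m],
        subject_id = meas$subject_id[m],
        cohort = "paediatric", polarity = "+", batch = meas$batch[m],
        scan_times = times, centroids = centroids, tic = tic,
        clinical = clinical_row(meas[m, ])
      )
    })
  })
  list(measurements = measurements, truth = new_synthetic_truth(design))
}

clinical_row <- function(m) {
  tibble(
    drugs = if (m$on_vpa) "VPA" else "LEV",
    total_vpa_mgL = m$total_vpa_mgL, free_vpa_mgL = m$free_vpa_mgL,
    side_effects_class = m$side_effects_class,
    response_class = m$response_class, eeg_class = m$eeg_class
  )
}

# ---- feature-level rendering ----------------------------------------------

#' Simulate the post-extraction mean-nAUC feature matrix directly
#'
#' Renders the measurements x features matrix that trace extraction would
#' produce, using the same amplitude model as [simulate_cohort()] but without
#' scan-level rendering: per exhalation, nAUC = pulse amplitude times the
#' window-average pulse shape times log-normal noise, averaged over
#' exhalations. Intended for statistically heavy simulations where hundreds
#' of cohorts are needed.
#'
#' @inheritParams simulate_cohort
#' @param detect_threshold Relative pulse-profile threshold defining the
#'   integration window (matches the default exhalation-detection threshold).
#' @param breath_filtered Emulate the breath-correlation filter by dropping
#'   the non-breath-correlated nuisance features from the table (default),
#'   matching the stage the scan-level extraction delivers. Set `FALSE` to
#'   keep them (e.g. to study the filters themselves).
#' @return A list with `feature_table` (a [feature_table]) and `truth`.
#' @export
simulate_feature_matrix <- function(config, pathway_db = NULL,
                                    detect_threshold = 0.3,
                                    breath_filtered = TRUE) {
  design <- simulate_design(config, pathway_db)
  cfg <- design$config
  meas <- design$measurements
  feats <- design$features
  nf <- nrow(feats)
  nm <- nrow(meas)
  nauc <- with_seed(cfg$seed + 2L, {
    out <- matrix(0, nm, nf, dimnames = dimnames(design$presence))
    for (m in seq_len(nm)) {
      sched <- meas$schedule[[m]]
      win <- profile_windows(sched, cfg$ramp_s, detect_threshold)
      # window-average of the unit pulse over each detected window
      times <- seq(min(win$start_s), max(win$end_s), by = 0.1)
      prof <- exhalation_profile(times, sched, cfg$ramp_s)
      wbar <- vapply(seq_len(nrow(win)), function(k) {
        i <- times >= win$start_s[k] & times <= win$end_s[k]
        mean(prof[i])
      }, numeric(1))
      k <- nrow(sched)
      eps <- matrix(rlnorm_cv(k * nf, cfg$noise_cv), k, nf)
      pulse_amp <- design$amplitude[m, ] + design$pulse_background[m, ]
      bc <- feats$breath_correlated
      v <- numeric(nf)
      v[bc] <- feats$floor[bc] +
        colMeans(eps[, bc, drop = FALSE] * outer(wbar, pulse_amp[bc]))
      v[!bc] <- design$amplitude[m, !bc] *
        rlnorm_cv(sum(!bc), cfg$noise_cv / sqrt(max(k * 10, 1)))
      v[!design$presence[m, ]] <- 0
      out[m, ] <- v
    }
    out
  })
  row_data <- bind_rows(lapply(seq_len(nm), function(m) clinical_row(meas[m, ]))) |>
    mutate(measurement_id = meas$measurement_id, subject_id = meas$subject_id,
           cohort = "paediatric", batch = meas$batch, .before = 1)
  col_data <- tibble(feature_id = feats$feature_id, mz = feats$mz,
                     polarity = "+", tol_ppm = 5)
  ft <- new_feature_table(nauc = nauc, presence = design$presence & nauc > 0,
                          row_data = row_data, col_data = col_data)
  if (breath_filtered) ft <- ft[, feats$breath_correlated]
  list(feature_table = ft, truth = new_synthetic_truth(design))
}
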