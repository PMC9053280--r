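test_that("cohort generation is deterministic given the seed and diverges across seeds", {
  a <- simulate_cohort(clean_cfg)
  expect_identical(a$measurements[[1]]$centroids,
                   clean_sim$measurements[[1]]$centroids)
  expect_identical(a$truth$measurements$total_vpa_mgL,
                   clean_sim$truth$measurements$total_vpa_mgL)
  other <- simulate_cohort(cohort_config(
    n_subjects = 4, visits_per_subject = 2, n_endogenous_features = 8,
    n_nuisance_features = 6, noise_cv = 0, mz_jitter_ppm = 0,
    n_batches = 1, batch_scale_sd = 0, seed = 8
  ))
  expect_false(identical(other$measurements[[1]]$tic,
                         clean_sim$measurements[[1]]$tic))
})

test_that("programmed concentrations respect free <= total and level 0 for non-takers", {
  tm <- tiny_sim$truth$measurements
  expect_true(all(tm$free_vpa_mgL <= tm$total_vpa_mgL + 1e-12))
  expect_true(all(tm$total_vpa_mgL[!tm$on_vpa] == 0))
  expect_true(all(tm$free_vpa_mgL[!tm$on_vpa] == 0))
  expect_true(all(tm$total_vpa_mgL[tm$on_vpa] > 0))
})

test_that("zero-noise drug-feature plateaus equal programmed amplitude plus background, proportional to free VPA", {
  truth <- clean_sim$truth
  feats <- truth$features
  drug_idx <- which(feats$kind == "drug")
  for (m in seq_along(clean_sim$measurements)) {
    meas <- clean_sim$measurements[[m]]
    prof <- exhalation_profile(meas$scan_times,
                               truth$measurements$schedule[[m]],
                               clean_cfg$ramp_s)
    plateau <- prof >= 1 - 1e-9
    for (j in drug_idx[c(1, 4, 9)]) {
      if (!truth$presence[m, j]) next
      trace <- extract_trace(meas, feats$mz[j], tol_ppm = 2)
      amp_obs <- mean(trace[plateau]) - feats$floor[j]
      amp_true <- truth$amplitude[m, j] + truth$pulse_background[m, j]
      expect_equal(amp_obs, amp_true, tolerance = 1e-10)
    }
  }
  # within a subject, amplitude above background is proportional to free VPA
  # (single batch, zero noise; the subject's metabolic factor is the constant)
  tm <- truth$measurements
  for (s in unique(tm$subject_id[tm$on_vpa])) {
    rows <- which(tm$subject_id == s & tm$on_vpa)
    if (length(rows) < 2) next
    j <- drug_idx[1]
    ratio <- truth$amplitude[rows, j] / tm$free_vpa_mgL[rows]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  }
})

test_that("frac_vpa = 0 leaves drug features at their background amplitude", {
  sim0 <- simulate_cohort(cohort_config(
    n_subjects = 3, visits_per_subject = 1, frac_vpa = 0,
    n_endogenous_features = 5, n_nuisance_features = 5, noise_cv = 0,
    mz_jitter_ppm = 0, n_batches = 1, batch_scale_sd = 0, seed = 11
  ))
  truth <- sim0$truth
  drug <- truth$features$kind == "drug"
  expect_true(all(truth$amplitude[, drug] == 0))
  expect_true(all(truth$measurements$total_vpa_mgL == 0))
})

test_that("rejects non-finite or out-of-range configurations", {
  expect_error(cohort_config(noise_cv = NaN), "non-finite")
  expect_error(cohort_config(effect_size_side_effects = Inf), "non-finite")
  expect_error(cohort_config(frac_vpa = 1.5), "frac_vpa")
  expect_error(cohort_config(noise_cv = -0.1), "noise_cv")
  expect_error(cohort_config(n_subjects = 0), "count")
})

test_that("rendered TIC pulses match the programmed exhalation schedule", {
  truth <- clean_sim$truth
  for (m in seq_along(clean_sim$measurements)) {
    meas <- clean_sim$measurements[[m]]
    sched <- truth$measurements$schedule[[m]]
    win <- detect_exhalations(meas$tic, meas$scan_times)
    expect_equal(nrow(win), truth$measurements$n_exhalations[m])
    # each detected window sits inside its programmed pulse extent
    expect_true(all(win$start_s >= sched$t_on - 1))
    expect_true(all(win$end_s <= sched$t_off + 1))
  }
})

test_that("breath-correlated traces are perfectly rank-correlated with the pulse profile at zero noise", {
  truth <- clean_sim$truth
  m <- 1
  meas <- clean_sim$measurements[[m]]
  prof <- exhalation_profile(meas$scan_times, truth$measurements$schedule[[m]],
                             clean_cfg$ramp_s)
  bc <- which(truth$features$breath_correlated & truth$presence[m, ])
  for (j in bc[seq(1, length(bc), by = 4)]) {
    trace <- extract_trace(meas, truth$features$mz[j], tol_ppm = 2)
    expect_equal(suppressWarnings(cor(rank(trace), rank(prof))), 1)
  }
})

test_that("nuisance-feature correlations with the exhalation indicator behave as under the null", {
  cfg <- cohort_config(n_subjects = 1, visits_per_subject = 1,
                       n_endogenous_features = 2, n_nuisance_features = 300,
                       noise_cv = 0.25, seed = 77)
  sim <- simulate_cohort(cfg)
  meas <- sim$measurements[[1]]
  win <- detect_exhalations(meas$tic, meas$scan_times)
  ind <- exhalation_indicator(meas$scan_times, win)
  nuis <- sim$truth$features[sim$truth$features$kind == "nuisance", ]
  nuis <- nuis[sim$truth$presence[1, nuis$feature_id], ]
  expect_gte(nrow(nuis), 200)
  pvals <- vapply(nuis$mz, function(mz) {
    tr <- extract_trace(meas, mz, tol_ppm = 3)
    breathtdm:::spearman_rho_p(tr, ind)[["p"]]
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("toy pathway databases have well-separated masses and unambiguous annotation", {
  db <- make_toy_pathway_db(n_pathways = 6, compounds_per_pathway = 5, seed = 3)
  m <- db$compounds$mass
  ppm <- abs(outer(m, m, "-")) / outer(rep(1, length(m)), m) * 1e6
  diag(ppm) <- Inf
  expect_true(all(ppm > 10)) # exhaustive pairwise check
  # annotating each exact [M+H]+ mass at 2 ppm returns exactly one compound
  feats <- tibble::tibble(feature_id = db$compounds$compound_id,
                          mz = db$compounds$mass + 1.00727646688)
  ann <- annotate_mz(feats, db, ppm_tol = 2)
  expect_equal(nrow(ann), nrow(feats))
  expect_identical(ann$feature_id, ann$compound_id)
})

test_that("toy databases embed the drug molecules outside the endogenous pathways", {
  db <- tiny_sim$truth$pathway_db
  drug <- db$compounds[db$compounds$is_drug, ]
  expect_equal(nrow(drug), 4)
  memb <- pathway_members(db)
  expect_false(any(drug$compound_id %in% memb$compound_id))
  # the protonated lactone lands on the published accurate mass
  lact <- drug$mass[drug$name == "4-OH-gamma-lactone"] + 1.00727646688
  expect_lt(abs(lact - 143.1066) / 143.1066 * 1e6, 2)
})

test_that("pathways can share compounds and tiny databases are well-formed", {
  db1 <- make_toy_pathway_db(n_pathways = 1, compounds_per_pathway = 3, seed = 5)
  memb1 <- pathway_members(db1)
  expect_equal(nrow(memb1), 3)
  expect_true(all(memb1$pathway_id == "P01"))
  db2 <- make_toy_pathway_db(n_pathways = 4, compounds_per_pathway = 5,
                             seed = 2, share_frac = 0.8)
  memb2 <- pathway_members(db2)
  shared <- names(which(table(memb2$compound_id) > 1))
  expect_gt(length(shared), 0)
  expect_gt(dplyr::n_distinct(memb2$pathway_id[memb2$compound_id == shared[1]]), 1)
})

test_that("feature-level rendering reproduces the design's class structure", {
  truth <- fm_default$truth
  ft <- fm_default$feature_table
  expect_equal(nrow(ft$nauc), 75)
  expect_equal(ncol(ft$nauc), sum(truth$features$breath_correlated))
  expect_true(all(ft$nauc >= 0))
  # affected features exist in both directions
  expect_gt(sum(truth$features$affected == "side_effects_up"), 0)
  expect_gt(sum(truth$features$affected == "nonresponse_down"), 0)
  # absent (not detected) entries are zero and masked
  expect_true(all(ft$nauc[!truth$presence[, colnames(ft$nauc)]] == 0))
})
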