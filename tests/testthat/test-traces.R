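test_that("exhalation detection finds programmed pulses and handles flat or merged input", {
  # 5 programmed pulses, zero noise: covered per-measurement in test-synth;
  # here the merge and degenerate rules on constructed TICs
  t <- seq(0, 100, by = 0.5)
  expect_equal(nrow(detect_exhalations(rep(5, length(t)), t)), 0)
  # two square pulses closer than min_gap_s merge into one window
  tic <- rep(1, length(t))
  tic[t >= 10 & t <= 20] <- 100
  tic[t >= 22 & t <= 32] <- 100
  win <- detect_exhalations(tic, t, min_gap_s = 3)
  expect_equal(nrow(win), 1)
  expect_equal(win$start_s, 10)
  expect_equal(win$end_s, 32)
  # with a wide enough gap they stay separate
  tic2 <- rep(1, length(t))
  tic2[t >= 10 & t <= 20] <- 100
  tic2[t >= 28 & t <= 38] <- 100
  expect_equal(nrow(detect_exhalations(tic2, t, min_gap_s = 3)), 2)
  # runs shorter than min_duration_s are dropped
  tic3 <- rep(1, length(t))
  tic3[t >= 10 & t <= 12] <- 100
  expect_equal(nrow(detect_exhalations(tic3, t, min_duration_s = 5)), 0)
  expect_error(detect_exhalations(c(1, NA, rep(1, 10)), seq_len(12)), "finite")
})

test_that("alignment recovers constructed shifts and conserves intensity", {
  set.seed(1)
  n <- 256
  ref <- dnorm(seq_len(n), 60, 4) * 100 + dnorm(seq_len(n), 150, 6) * 80
  shifted <- c(rep(0, 3), ref[1:(n - 3)]) # forward shift by +3 bins
  mat <- cbind(ref, shifted)
  out <- align_scans(mat, max_shift_bins = 10)
  expect_equal(out$shifts[1], 0) # identical to reference
  expect_equal(out$shifts[2], -3) # recovered correction
  expect_equal(out$aligned[, 2], ref, tolerance = 1e-8)
  # pure-noise scan: contract only - bounded shift, intensity conserved
  noise <- abs(rnorm(n))
  out2 <- align_scans(cbind(ref, noise), max_shift_bins = 10)
  expect_lte(abs(out2$shifts[2]), 10)
  expect_equal(sum(out2$aligned[, 2]), sum(noise), tolerance = 1e-12)
  expect_equal(colSums(out$aligned), colSums(mat), tolerance = 1e-12)
})

test_that("feature consolidation separates centroids and applies the presence rule", {
  mk <- function(id, mzs) {
    new_raw_measurement(
      measurement_id = id, scan_times = seq(0, 9),
      centroids = tibble::tibble(scan = rep(1:10, each = length(mzs)),
                                 mz = rep(mzs, 10) * (1 + rnorm(10 * length(mzs), 0, 2e-7)),
                                 intensity = 50)
    )
  }
  set.seed(4)
  mz_a <- 200
  mz_b <- 200 * (1 + 50e-6) # 50 ppm apart
  meas <- lapply(sprintf("M%02d", 1:20), mk, mzs = c(mz_a, mz_b))
  feats <- build_feature_list(meas, kde_bandwidth_ppm = 2, min_presence = 0.1)
  expect_equal(nrow(feats), 2)
  expect_lt(abs(feats$mz[1] - mz_a) / mz_a * 1e6, 2)
  expect_lt(abs(feats$mz[2] - mz_b) / mz_b * 1e6, 2)
  # a centroid present in only 1 of 20 measurements is dropped at 10%
  meas_rare <- c(lapply(sprintf("M%02d", 1:19), mk, mzs = mz_a),
                 list(mk("M20", c(mz_a, 300))))
  feats2 <- build_feature_list(meas_rare, kde_bandwidth_ppm = 2,
                               min_presence = 0.10)
  expect_equal(nrow(feats2), 1)
  expect_lt(abs(feats2$mz - mz_a), 0.01)
  expect_equal(nrow(build_feature_list(list())), 0)
  expect_error(build_feature_list(meas, kde_bandwidth_ppm = 0), "bandwidth")
})

test_that("trace extraction sums in-window centroids and respects tolerance", {
  m <- new_raw_measurement(
    measurement_id = "M1", scan_times = c(0, 1, 2),
    centroids = tibble::tibble(
      scan = c(1, 2, 2, 3),
      mz = c(200, 200 * (1 + 1e-6), 200 * (1 - 1e-6), 200 * (1 + 3e-6)),
      intensity = c(100, 60, 40, 100)
    )
  )
  expect_equal(extract_trace(m, 200, tol_ppm = 2), c(100, 100, 0))
})

test_that("breath-correlation filter keeps monotone traces and rejects anti- or un-correlated ones", {
  ind <- rep(c(0, 1), times = 25)
  tr <- cbind(
    same = ind,
    anti = 1 - ind,
    const = rep(2, 50)
  )
  rep1 <- breath_correlation_filter(list(tr), list(ind))
  expect_true(rep1$keep[rep1$feature_id == "same"])
  expect_false(rep1$keep[rep1$feature_id == "anti"]) # rho = -1 < 0.6
  expect_false(rep1$keep[rep1$feature_id == "const"]) # undefined rho fails
  expect_equal(rep1$min_rho[rep1$feature_id == "same"], 1)
  # the every-measurement rule: failing in one measurement drops the feature
  tr2 <- cbind(same = rev(ind), anti = 1 - ind, const = rep(2, 50))
  rep2 <- breath_correlation_filter(list(tr, tr2), list(ind, ind))
  expect_false(rep2$keep[rep2$feature_id == "same"])
  # quorum relaxes it
  rep3 <- breath_correlation_filter(list(tr, tr, tr2), list(ind, ind, ind),
                                    quorum = 0.6)
  expect_true(rep3$keep[rep3$feature_id == "same"])
})

test_that("nAUC matches the trapezoid oracle, is exact on plateaus and scales linearly", {
  t <- seq(0, 100, by = 0.5)
  win <- tibble::tibble(start_s = c(10, 40, 70), end_s = c(25, 55, 85))
  # rectangular plateau of height 10 across every window: nAUC = 10 exactly
  plateau <- rep(10, length(t))
  expect_identical(compute_nauc(plateau, t, win), 10)
  expect_identical(compute_nauc(rep(0, length(t)), t, win), 0)
  # piecewise-constant windows {8, 10, 12} -> mean 10
  tr <- numeric(length(t))
  tr[t >= 10 & t <= 25] <- 8
  tr[t >= 40 & t <= 55] <- 10
  tr[t >= 70 & t <= 85] <- 12
  expect_equal(compute_nauc(tr, t, win), 10)
  # random trace vs independent oracle
  set.seed(2)
  for (i in 1:5) {
    tr <- abs(rnorm(length(t))) * 10
    expect_equal(compute_nauc(tr, t, win), nauc_oracle(tr, t, win),
                 tolerance = 1e-12)
  }
  # linear scaling is exact
  expect_equal(compute_nauc(3.7 * tr, t, win), 3.7 * compute_nauc(tr, t, win),
               tolerance = 1e-12)
  expect_error(compute_nauc(tr, t, tibble::tibble(start_s = 5, end_s = 5)),
               "end_s")
})

test_that("feature-table assembly matches hand-computed values and logs failures", {
  mk <- function(id, heights, flat = FALSE) {
    t <- seq(0, 120, by = 0.5)
    tr1 <- numeric(length(t)); tr2 <- numeric(length(t))
    tr1[t >= 10 & t <= 25] <- heights[1]
    tr1[t >= 50 & t <= 65] <- heights[1]
    tr2[t >= 10 & t <= 25] <- heights[2]
    tr2[t >= 50 & t <= 65] <- heights[2]
    if (flat) { tr1[] <- 0; tr2[] <- 0 }
    cc <- dplyr::bind_rows(
      tibble::tibble(scan = which(tr1 > 0), mz = 150, intensity = tr1[tr1 > 0]),
      tibble::tibble(scan = which(tr2 > 0), mz = 250, intensity = tr2[tr2 > 0])
    )
    new_raw_measurement(measurement_id = id, scan_times = t, centroids = cc,
                        tic = tr1 + tr2 + 1)
  }
  feats <- tibble::tibble(feature_id = c("A", "B"), mz = c(150, 250),
                          polarity = "+", tol_ppm = 5)
  meas <- list(mk("M1", c(10, 20)), mk("M2", c(5, 40)), mk("M3", c(8, 16)),
               mk("M4", c(0, 0), flat = TRUE))
  ft <- assemble_feature_table(meas, feats)
  expect_equal(dim(ft$nauc), c(3, 2))
  expect_equal(unname(ft$nauc[, "A"]), c(10, 5, 8))
  expect_equal(unname(ft$nauc[, "B"]), c(20, 40, 16))
  expect_equal(ft$failed$measurement_id, "M4")
  expect_match(ft$failed$reason, "exhalation")
  expect_error(assemble_feature_table(meas, feats[0, ]), "empty feature list")
  expect_error(assemble_feature_table(list(meas[[1]], meas[[1]]), feats),
               "duplicate")
})

test_that("nAUC is stable under scan-rate refinement", {
  sched <- tibble::tibble(t_on = c(10, 40), t_off = c(30, 60))
  win <- tibble::tibble(start_s = c(11, 41), end_s = c(29, 59))
  for (hz in c(2, 4)) {
    t <- seq(0, 70, by = 1 / hz)
    tr <- 100 * exhalation_profile(t, sched, ramp_s = 2)
    assign(paste0("n", hz), compute_nauc(tr, t, win))
  }
  expect_lt(abs(n4 - n2) / n2, 0.005)
})
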