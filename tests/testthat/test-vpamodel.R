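test_that("drug-feature filter applies the presence rule among VPA measurements only", {
  set.seed(1)
  nauc <- matrix(1, 20, 2, dimnames = list(NULL, c("hi", "lo")))
  nauc[1:1, "hi"] <- 0 # 9/10 among VPA rows
  nauc[1:3, "lo"] <- 0 # 7/10 among VPA rows
  nauc[11:20, ] <- 1 # non-VPA rows present everywhere (irrelevant)
  ft <- make_ft(nauc, total_vpa = rep(c(80, 0), each = 10))
  kept <- filter_drug_features(ft, min_presence = 0.8)
  expect_identical(colnames(kept$nauc), "hi")
  ft0 <- make_ft(nauc, total_vpa = rep(0, 20))
  expect_error(filter_drug_features(ft0), "no VPA measurements")
})

test_that("RReliefF ranks a noiseless monotone predictor first and respects symmetry", {
  set.seed(10)
  n <- 200
  X <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, paste0("V", 1:10)))
  y <- 3 * X[, 1]
  w <- rrelieff_weights(X, y, k_neighbors = 10)
  expect_equal(names(which.max(w)), "V1")
  expect_gt(w["V1"], max(w[-1]) + 0.05)
  # duplicated columns get equal weights
  X2 <- cbind(X[, 1:3], dup = X[, 1])
  colnames(X2) <- c("a", "b", "c", "dup")
  w2 <- rrelieff_weights(X2, y, k_neighbors = 10)
  expect_equal(unname(w2["a"]), unname(w2["dup"]), tolerance = 1e-12)
  expect_identical(rrelieff_weights(X, rep(5, n), k_neighbors = 10),
                   stats::setNames(numeric(10), colnames(X)))
  expect_error(rrelieff_weights(X, y, k_neighbors = n), "k_neighbors")
})

test_that("forest importance finds the signal feature and vanishes for a constant target", {
  set.seed(3)
  n <- 150
  X <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, paste0("V", 1:10)))
  y <- sin(2 * pi * X[, 1]) + rnorm(n, 0, 0.05)
  hits <- vapply(1:10, function(s) {
    names(which.max(forest_importance(X, y, seed = s))) == "V1"
  }, logical(1))
  expect_true(all(hits))
  expect_true(all(forest_importance(X, rep(1, n), seed = 1) == 0))
  # joint row permutation leaves the ranking intact (exchangeability)
  perm <- sample(n)
  ip <- forest_importance(X[perm, ], y[perm], seed = 1)
  expect_identical(names(which.max(ip)), "V1")
})

test_that("importance combination follows the stated min-max / mean / renormalise convention", {
  r1 <- combine_and_select(c(a = 1, b = 0), c(a = 1, b = 0), cutoff = 0.1)
  expect_equal(r1$combined_weight, c(1, 0))
  expect_equal(r1$selected, c(TRUE, FALSE))
  # disagreeing methods: (0.5, 0.5) renormalised to (1, 1), both selected
  r2 <- combine_and_select(c(a = 1, b = 0), c(a = 0, b = 1), cutoff = 0.1)
  expect_equal(r2$combined_weight, c(1, 1))
  expect_true(all(r2$selected))
  # strict inequality at the boundary
  r3 <- combine_and_select(c(1, 0), c(1, 0), cutoff = 1.0)
  expect_false(any(r3$selected))
  # an all-equal vector contributes 0.5 uniformly
  r4 <- combine_and_select(c(2, 2, 2), c(1, 0, 0), cutoff = 0.1)
  expect_equal(r4$relief_weight, rep(0.5, 3))
  expect_equal(max(r4$combined_weight), 1)
})

test_that("batch adjustment is a no-op on one batch and errors on undersized batches", {
  X <- matrix(rnorm(60, 10), 20, 3)
  expect_equal(combat_adjust(X, rep("B1", 20)), X, ignore_attr = TRUE)
  expect_error(combat_adjust(X, c(rep("A", 19), "Z")), "Z")
})

test_that("a single empirical-Bayes pass reproduces the reference sva algorithm", {
  set.seed(21)
  n <- 40; p <- 25
  X <- matrix(rlnorm(n * p, 2, 0.4), n, p, dimnames = list(NULL, paste0("F", 1:p)))
  batch <- rep(c("A", "B"), each = n / 2)
  X[batch == "B", ] <- X[batch == "B", ] *
    matrix(rep(rlnorm(p, 0, 0.3), each = n / 2), n / 2, p)
  mine <- combat_adjust(X, batch, max_iter = 1, preserve_moments = FALSE)
  ref <- t(suppressMessages(sva::ComBat(t(X), batch = batch)))
  expect_equal(unclass(mine), ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("batch adjustment homogenises variances across batches on null features", {
  set.seed(31)
  n <- 120; p <- 100
  batch <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * p, 50, 5), n, p, dimnames = list(NULL, paste0("F", 1:p)))
  scales <- rlnorm(p, 0, 0.25)
  X[batch == "B", ] <- 50 + sweep(X[batch == "B", ] - 50, 2, scales, "*")
  Xa <- combat_adjust(X, batch)
  pf <- vapply(seq_len(p), function(j) {
    stats::var.test(Xa[batch == "A", j], Xa[batch == "B", j])$p.value
  }, numeric(1))
  expect_gte(mean(pf > 0.05), 0.9)
})

test_that("eGPR interpolates at vanishing noise and the kernel behaves", {
  set.seed(5)
  X <- matrix(runif(30), 15, 2)
  y <- rowSums(X) + rnorm(15, 0, 0.01)
  fit <- fit_egpr(X, y, hyper = list(sigma_f2 = 2, length_scale = 1,
                                     sigma_n2 = 0), jitter = 1e-12)
  expect_equal(predict(fit, X, clip_negative = FALSE), y, tolerance = 1e-6)
  D <- as.matrix(dist(matrix(rnorm(20), 10)))
  K <- exp_kernel(D, sigma_f2 = 3, length_scale = 2)
  expect_true(all(diag(K) == 3))
  o <- order(D[1, ])
  expect_true(all(diff(K[1, o]) <= 1e-12))
})

test_that("eGPR recovers a smooth nonlinear signal on held-out data", {
  set.seed(6)
  n <- 90
  X <- matrix(runif(n, -2, 2), n, 1)
  y <- 40 + 30 * tanh(X[, 1]) + rnorm(n, 0, 1.5)
  tr <- seq_len(n) <= 60
  fit <- fit_egpr(X[tr, , drop = FALSE], y[tr], restarts = 4, seed = 1)
  cc <- lin_ccc(y[!tr], predict(fit, X[!tr, , drop = FALSE]))$ccc
  expect_gt(cc, 0.9)
})

test_that("Lin's CCC matches hand-derived cases and degenerate conventions", {
  x <- rnorm(20)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1))$ccc, -1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 4, 6))$ccc, 4 / 11, tolerance = 1e-12)
  expect_equal(lin_ccc(c(2, 2), c(2, 2))$ccc, 1) # both constant, equal means
  expect_equal(lin_ccc(c(2, 2), c(3, 3))$ccc, 0)
  expect_equal(lin_ccc(c(1, 2, 3), c(5, 5, 5))$ccc, 0)
})

test_that("|CCC| <= |Pearson r| with equality exactly when moments match", {
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(30) + 0.5 * x
    r <- lin_ccc(x, y)
    expect_lte(abs(r$ccc), abs(r$pearson_r) + 1e-12)
  }
  # identical affine transform of identical vectors preserves perfect agreement
  x <- rnorm(25)
  expect_equal(lin_ccc(3 * x + 7, 3 * x + 7)$ccc, 1)
})

test_that("regressor screening ranks the GP above ridge on a smooth nonlinear target", {
  set.seed(9)
  wins <- vapply(1:8, function(s) {
    n <- 60
    X <- matrix(runif(n * 2, -2, 2), n, 2)
    y <- 30 * sin(2 * X[, 1]) + rnorm(n, 0, 1) # non-monotone: linear fits fail

    fams <- default_regressor_families()[c("egpr", "ridge")]
    fams$egpr$fit <- function(X, y) fit_egpr(X, y, restarts = 2)
    tab <- screen_regressors(X, y, folds = 4, seeds = s, families = fams)
    tab$family[1] == "egpr"
  }, logical(1))
  expect_gte(sum(wins), 7)
  # a single registered family yields a single-row table
  one <- screen_regressors(matrix(rnorm(40), 20), rnorm(20), folds = 4,
                           seeds = 1,
                           families = default_regressor_families()["ridge"])
  expect_equal(nrow(one), 1)
  expect_error(screen_regressors(matrix(rnorm(10), 5), rnorm(5), folds = 6),
               "folds")
})

test_that("pathway-activity ratios propagate missingness and recover subject heterogeneity", {
  nauc <- matrix(c(20, 30, 5, 10, 15, 0), 3, 2,
                 dimnames = list(NULL, c("num", "den")))
  ft <- make_ft(nauc, subject = c("S1", "S1", "S2"))
  r <- pathway_activity_ratio(ft, "num", "den")
  expect_equal(r$ratio, c(2, 2, NA))
  smry <- subject_ratio_summary(r)
  expect_equal(smry$subject_id, "S1")
  expect_equal(smry$median_ratio, 2)
  expect_error(pathway_activity_ratio(ft, "num", "nope"), "nope")

  # programmed per-subject beta/omega activity is recovered from the
  # 3-heptanone / 4-OH-gamma-lactone nAUC ratio
  sm <- simulate_feature_matrix(cohort_config(
    seed = 55, noise_cv = 0.15, n_batches = 1, batch_scale_sd = 0,
    frac_vpa = 1
  ))
  truth <- sm$truth
  hept <- truth$features$feature_id[which(truth$features$molecule == "3-heptanone")[1]]
  lact <- truth$features$feature_id[which(truth$features$molecule == "4-OH-gamma-lactone")[1]]
  rat <- pathway_activity_ratio(sm$feature_table, hept, lact)
  rec <- subject_ratio_summary(rat)
  prog <- truth$subjects$beta_ox / truth$subjects$omega_ox
  names(prog) <- truth$subjects$subject_id
  expect_gte(suppressWarnings(cor(rec$median_ratio, prog[rec$subject_id],
                                  method = "spearman")), 0.9)
})
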