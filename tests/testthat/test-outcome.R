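test_that("endogenous filter applies the presence and CV rules", {
  nauc <- cbind(
    flat = rep(10, 10), # CV = 0 -> dropped
    varia = c(5, 10, 15, 5, 10, 15, 5, 10, 15, 10), # CV = 41% -> kept
    rare = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0) # present 4/10 -> dropped
  )
  ft <- make_ft(nauc)
  kept <- filter_endogenous(ft, min_presence = 0.5, min_cv = 0.3)
  expect_identical(colnames(kept$nauc), "varia")
  # hand arithmetic of the CV rule: (5,10,15) -> sample SD 5, mean 10, CV 50%
  ft2 <- make_ft(cbind(x = c(5, 10, 15)))
  expect_equal(ncol(filter_endogenous(ft2, min_presence = 0.5,
                                      min_cv = 0.3)$nauc), 1)
  expect_equal(ncol(filter_endogenous(ft2, min_presence = 0.5,
                                      min_cv = 0.51)$nauc), 0)
})

test_that("differential abundance handles identical groups, BH arithmetic and zero variance", {
  X <- matrix(rep(c(4, 7, 9, 12), 3), 4, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  d <- differential_abundance(rbind(X, X), rep(c(FALSE, TRUE), each = 4))
  expect_equal(d$t, rep(0, 3))
  expect_equal(d$p, rep(1, 3))
  expect_equal(d$log2fc, rep(0, 3))
  # BH step-up hand computation
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
  # zero-variance group at n = 2: flagged, df floored
  Xz <- cbind(z = c(1, 1, 5, 9), w = c(1, 2, 5, 9))
  dz <- differential_abundance(Xz, c(FALSE, FALSE, TRUE, TRUE))
  expect_true(dz$flagged[dz$feature_id == "z"])
  expect_false(dz$flagged[dz$feature_id == "w"])
  expect_true(all(dz$q >= dz$p))
})

test_that("BH q-values equal the independent step-up oracle on random vectors", {
  set.seed(12)
  for (n in c(1, 2, 5, 12, 20)) {
    for (rep in 1:20) {
      p <- round(runif(n), 3)
      expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
  }
})

test_that("Welch differential testing attains power on a programmed shift", {
  set.seed(13)
  n1 <- 40; n2 <- 35; p <- 40
  affected <- seq_len(25)
  X <- matrix(rlnorm((n1 + n2) * p, log(100), 0.4), n1 + n2, p,
              dimnames = list(NULL, sprintf("F%03d", 1:p)))
  X[(n1 + 1):(n1 + n2), affected] <- X[(n1 + 1):(n1 + n2), affected] * 1.5
  d <- differential_abundance(X, rep(c(FALSE, TRUE), c(n1, n2)))
  expect_gte(mean(d$q[affected] < 0.1), 0.8)
  expect_true(all(d$log2fc[affected] > 0))
})

test_that("accurate-mass annotation matches known adduct arithmetic and keeps isomers", {
  db <- tiny_sim$truth$pathway_db
  # protonated 3-heptanone: neutral 114.1045 + 1.007276 -> ~115.1117
  f <- tibble::tibble(feature_id = "hept", mz = 115.1117)
  ann <- annotate_mz(f, db, ppm_tol = 2)
  expect_equal(nrow(ann), 1)
  expect_equal(db$compounds$name[db$compounds$compound_id == ann$compound_id],
               "3-heptanone")
  # 5 ppm off: no match at 2 ppm
  f5 <- tibble::tibble(feature_id = "off", mz = 115.1117 * (1 + 5e-6))
  expect_equal(nrow(annotate_mz(f5, db, ppm_tol = 2)), 0)
  # two isomeric compounds: both retained
  iso_db <- structure(list(
    compounds = tibble::tibble(
      compound_id = c("X1", "X2"), name = c("iso a", "iso b"),
      mass = c(150.1, 150.1), is_drug = FALSE),
    pathways = tibble::tibble(pathway_id = "P01", name = "p",
                              compound_ids = list(c("X1", "X2")))
  ), class = "pathway_db")
  fi <- tibble::tibble(feature_id = "i", mz = 150.1 + 1.00727646688)
  expect_equal(sort(annotate_mz(fi, iso_db, ppm_tol = 2)$compound_id),
               c("X1", "X2"))
})

test_that("a spiked pathway attains the minimal permutation p and empty input degenerates to 1", {
  db <- make_toy_pathway_db(n_pathways = 5, compounds_per_pathway = 6,
                            seed = 9, share_frac = 0)
  memb <- pathway_members(db)
  cpd <- db$compounds
  bg <- tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(nrow(cpd))),
    mz = cpd$mass + 1.00727646688
  )
  spike <- memb$compound_id[memb$pathway_id == "P03"]
  sig <- bg[match(spike, cpd$compound_id), ]
  mm <- mummichog_enrichment(sig, bg, db, n_perm = 199, seed = 1)
  expect_equal(mm$p_mummichog[mm$pathway_id == "P03"], 1 / 200)
  expect_equal(mm$hits[mm$pathway_id == "P03"], length(spike))
  # randomized tie-breaking can only be at most the conservative value
  mmr <- mummichog_enrichment(sig, bg, db, n_perm = 199, seed = 1,
                              tie_break = "randomized")
  expect_lte(mmr$p_mummichog[mmr$pathway_id == "P03"], 1 / 200)
  # empty significant list: everything at p = 1
  mm0 <- mummichog_enrichment(sig[0, ], bg, db, n_perm = 199, seed = 1)
  expect_true(all(mm0$p_mummichog == 1))
  # a pathway absent from the background is excluded and reported
  bg_part <- bg[bg$feature_id %in%
                  bg$feature_id[match(memb$compound_id[memb$pathway_id %in%
                                                         c("P01", "P03")],
                                      cpd$compound_id)], ]
  sig_part <- sig[sig$feature_id %in% bg_part$feature_id, ]
  mmp <- mummichog_enrichment(sig_part, bg_part, db, n_perm = 199, seed = 1)
  expect_false("P02" %in% mmp$pathway_id)
  expect_true("P02" %in% attr(mmp, "excluded"))
  expect_error(mummichog_enrichment(bg, sig, db), "subset")
})

test_that("GSEA running sum matches a brute-force oracle at weight 0 and detects a top-loaded set", {
  # 10-feature toy, unweighted: independent running-sum oracle
  scores <- c(a = 5, b = 4, c = 3, d = 2.5, e = 2, f = 1.5, g = 1, h = 0.5,
              i = -1, j = -2)
  members <- c("b", "c", "g")
  oracle_es <- function(ranked, members) {
    inset <- ranked %in% members
    run <- cumsum(ifelse(inset, 1 / sum(inset), -1 / sum(!inset)))
    run[which.max(abs(run))]
  }
  db <- structure(list(
    compounds = tibble::tibble(compound_id = paste0("c_", names(scores)),
                               name = names(scores),
                               mass = 150 + seq_along(scores), is_drug = FALSE),
    pathways = tibble::tibble(pathway_id = "P01", name = "toy",
                              compound_ids = list(paste0("c_", members)))
  ), class = "pathway_db")
  ann <- tibble::tibble(feature_id = names(scores),
                        compound_id = paste0("c_", names(scores)))
  g0 <- gsea_enrichment(scores, ann, db, n_perm = 200, seed = 1, weight = 0)
  expect_equal(g0$es, oracle_es(names(sort(scores, decreasing = TRUE)), members),
               tolerance = 1e-12)
  # all members at the top of the ranking: maximal ES, minimal p
  db2 <- db
  db2$pathways$compound_ids <- list(paste0("c_", c("a", "b", "c")))
  g1 <- gsea_enrichment(scores, ann, db2, n_perm = 199, seed = 2, weight = 1)
  expect_equal(g1$p_gsea, 1 / 200)
  expect_gt(g1$es, 0.9)
  # pathways with < 2 annotated features are excluded
  db3 <- db
  db3$pathways$compound_ids <- list("c_a")
  expect_equal(nrow(gsea_enrichment(scores, ann, db3, n_perm = 100, seed = 1)), 0)
})

test_that("dual-significance selection uses strict inequalities", {
  enr <- tibble::tibble(pathway_id = c("A", "B", "C"),
                        p_mummichog = c(0.01, 0.01, 0.05),
                        p_gsea = c(0.01, 0.20, 0.01))
  sel <- select_enriched(enr, alpha = 0.05)
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE))
})

test_that("Youden cutoff matches the brute-force scan and the PC1 model separates classes", {
  set.seed(14)
  for (i in 1:25) {
    sc <- rnorm(60)
    lab <- runif(60) < 0.4
    if (!any(lab) || all(lab)) next
    expect_equal(youden_cutoff(sc, lab)$j, youden_oracle(sc, lab),
                 tolerance = 1e-12)
  }
  # two well-separated Gaussian score populations
  sc <- c(rnorm(100, 0), rnorm(100, 3))
  lab <- rep(c(FALSE, TRUE), each = 100)
  yc <- youden_cutoff(sc, lab)
  expect_gte(yc$j, 0.8)
  expect_gte(yc$cutoff, 1.0)
  expect_lte(yc$cutoff, 2.0)
  # perfectly separated scores
  expect_equal(youden_cutoff(c(1, 2, 3, 10, 11, 12),
                             rep(c(FALSE, TRUE), each = 3))$j, 1)
})

test_that("the outcome-score model fits, predicts and validates its inputs", {
  set.seed(15)
  n <- 100
  lab <- rep(c(FALSE, TRUE), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[lab, ] <- X[lab, ] + 2.5
  m <- fit_outcome_score(X, lab)
  expect_equal(sum(m$loadings^2), 1, tolerance = 1e-12)
  expect_gte(m$youden_j, 0.8)
  # projecting the training matrix reproduces the training scores
  pr <- predict(m, X)
  expect_equal(pr$score, m$train_scores, tolerance = 1e-12)
  # a new sample at the training mean scores 0
  pr0 <- predict(m, matrix(m$center, 1, dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(pr0$score, 0, tolerance = 1e-12)
  expect_error(predict(m, X[, 1:2]), "c")
  expect_error(fit_outcome_score(X[, 1, drop = FALSE], lab), "2 member")
})

test_that("null labels rarely reach a high Youden J", {
  set.seed(16)
  js <- vapply(1:40, function(i) {
    sc <- rnorm(200)
    lab <- rep(c(FALSE, TRUE), each = 100)
    youden_cutoff(sc, lab)$j
  }, numeric(1))
  expect_gte(mean(js <= 0.25), 0.95)
})

test_that("PC1 explains at least as much variance as random directions", {
  set.seed(17)
  X <- matrix(rnorm(300), 100, 3)
  X[, 2] <- X[, 1] * 0.8 + rnorm(100, 0, 0.3)
  Xs <- scale(X)
  v1 <- eigen(stats::cov(Xs), symmetric = TRUE)$vectors[, 1]
  var1 <- stats::var(as.numeric(Xs %*% v1))
  for (i in 1:30) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    expect_lte(stats::var(as.numeric(Xs %*% u)), var1 + 1e-10)
  }
})

test_that("the full outcome workflow recovers the programmed side-effect pathways", {
  ft <- fm_default$feature_table
  truth <- fm_default$truth
  ow <- outcome_workflow(ft, "side_effects", truth$pathway_db, n_perm = 150,
                         seed = 3)
  sel <- ow$enrichment$pathway_id[ow$enrichment$selected]
  expect_true(all(sel %in% truth$affected_pathways$side_effects))
  expect_gt(length(ow$members), 1)
  expect_false(is.null(ow$model))
})
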