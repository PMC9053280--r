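# Drug-modulated endogenous metabolites -> outcome scores: variability
# filter, Welch differential testing with BH correction, accurate-mass and
# GSEA pathway enrichment, and the PC1/Youden classifier.

#' Filter endogenous (drug-regulated) features
#'
#' Keeps features present in at least `min_presence` of all measurements and
#' whose coefficient of variation (sample SD / mean of the nonzero nAUC
#' values) is strictly greater than `min_cv`.
#'
#' @param ft A [feature_table].
#' @param min_presence Presence fraction across all measurements (default 0.5).
#' @param min_cv CV threshold (default 0.30, i.e. 30%).
#' @return The filtered `feature_table`.
#' @export
filter_endogenous <- function(ft, min_presence = 0.5, min_cv = 0.3) {
  stopifnot(inherits(ft, "feature_table"))
  pres <- presence_fraction(ft)
  cv <- apply(ft$nauc, 2, function(x) {
    x <- x[x > 0]
    if (length(x) < 2 || mean(x) == 0) return(0)
    sd(x) / mean(x)
  })
  ft[, pres >= min_presence & cv > min_cv]
}

# Welch two-sample t-test, vectorised over features, tolerant of
# zero-variance groups (df floored at 1, flagged).
welch_t <- function(X, positive) {
  n1 <- sum(!positive); n2 <- sum(positive)
  stopifnot(n1 >= 2, n2 >= 2)
  X1 <- X[!positive, , drop = FALSE]; X2 <- X[positive, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, var); v2 <- apply(X2, 2, var)
  se2 <- v1 / n1 + v2 / n2
  flagged <- v1 == 0 | v2 == 0
  t_stat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2),
                   ifelse(m2 == m1, 0, Inf * sign(m2 - m1)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  df <- pmax(df, 1)
  p <- ifelse(is.infinite(t_stat), 0,
              2 * pt(-abs(t_stat), df = df))
  p[se2 == 0 & m1 == m2] <- 1
  list(mean_ref = m1, mean_pos = m2, t = t_stat, df = df, p = p,
       flagged = flagged)
}

#' Differential abundance between outcome classes
#'
#' Welch two-sample t-test per feature comparing the positive class (II and
#' III combined) against class I, Benjamini-Hochberg adjusted; log2 fold
#' change of group means with a pseudo-count of 1% of the matrix's median
#' positive value.
#'
#' @param X Numeric matrix, measurements x features.
#' @param positive Logical per-measurement outcome (TRUE = class II/III);
#'   both groups need n >= 2.
#' @param values `"raw"` intensities (log2 fold change from the pseudo-counted
#'   ratio of group means) or already `"log2"`-transformed values (fold change
#'   is the difference of group means, no pseudo-count).
#' @return A `differential_result` tibble: `feature_id`, `mean_ref`,
#'   `mean_pos`, `log2fc`, `t`, `df`, `p`, `q`, `flagged` (zero-variance
#'   Welch fallback).
#' @export
differential_abundance <- function(X, positive, values = c("raw", "log2")) {
  values <- match.arg(values)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(positive), is.logical(positive))
  w <- welch_t(X, positive)
  lfc <- if (values == "log2") {
    w$mean_pos - w$mean_ref
  } else {
    posvals <- X[X > 0]
    eps <- if (length(posvals)) 0.01 * median(posvals) else 1e-9
    log2((w$mean_pos + eps) / (w$mean_ref + eps))
  }
  structure(
    tibble(
      feature_id = colnames(X) %||% sprintf("F%03d", seq_len(ncol(X))),
      mean_ref = unname(w$mean_ref), mean_pos = unname(w$mean_pos),
      log2fc = unname(lfc),
      t = unname(w$t), df = unname(w$df), p = unname(w$p),
      q = unname(p.adjust(w$p, method = "BH")),
      flagged = unname(w$flagged)
    ),
    class = c("differential_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Annotate feature m/z values against a pathway database
#'
#' Putative accurate-mass annotation: a feature matches a compound iff the
#' relative deviation between observed m/z and the adduct-shifted
#' monoisotopic mass is within `ppm_tol`. Multiple candidates (isomers) are
#' all retained.
#'
#' @param features Tibble with `feature_id` and `mz` columns.
#' @param db A `pathway_db`.
#' @param adducts Character vector among `"M+H"`, `"M-H"`, `"M+Na"`.
#' @param ppm_tol Tolerance (ppm), default 2.
#' @return Tibble: `feature_id`, `compound_id`, `adduct`, `ppm_error`.
#' @export
annotate_mz <- function(features, db, adducts = "M+H", ppm_tol = 2) {
  stopifnot(inherits(db, "pathway_db"), length(adducts) >= 1)
  shifts <- c("M+H" = PROTON_MASS, "M-H" = -PROTON_MASS, "M+Na" = NA_ADDUCT)
  stopifnot(all(adducts %in% names(shifts)))
  out <- list()
  for (ad in adducts) {
    theo <- db$compounds$mass + shifts[[ad]]
    for (i in seq_len(nrow(features))) {
      d <- ppm_diff(features$mz[i], theo)
      hit <- which(d <= ppm_tol)
      if (length(hit)) {
        out[[length(out) + 1]] <- tibble(
          feature_id = features$feature_id[i],
          compound_id = db$compounds$compound_id[hit],
          adduct = ad, ppm_error = d[hit]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(feature_id = character(), compound_id = character(),
                  adduct = character(), ppm_error = numeric()))
  }
  bind_rows(out)
}

#' Hypergeometric upper-tail enrichment probability
#'
#' `P(X >= k)` for X hypergeometric: the probability of at least `k` pathway
#' compounds among `n` drawn from a background of `N` compounds of which `K`
#' belong to the pathway. This is the per-pathway enrichment statistic of
#' [mummichog_enrichment()] (used there on the -log scale).
#'
#' @param k Observed hits.
#' @param K Pathway compounds in the background.
#' @param N Background size.
#' @param n Number drawn (annotated significant compounds).
#' @param log.p Return the log probability.
#' @return Numeric probability (vectorised over `k`, `K`).
#' @export
hypergeom_tail <- function(k, K, N, n, log.p = FALSE) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = log.p)
}

# pathway hit counts for a set of annotated compounds
pathway_hits <- function(compounds, memb) {
  memb |>
    filter(.data$compound_id %in% compounds) |>
    dplyr::count(.data$pathway_id, name = "hits")
}

#' Accurate-mass (mummichog-style) pathway enrichment
#'
#' Annotates the significant and background m/z lists, scores each pathway by
#' the hypergeometric upper tail of its significant-compound hits, and builds
#' the null by repeatedly drawing `|sig|` features at random from the
#' background. The permutation p-value uses the +1 correction. Because the
#' hit counts are integers the permutation statistic is discrete;
#' `tie_break = "conservative"` counts ties as exceedances (valid,
#' super-uniform), `"randomized"` breaks ties uniformly at random (exactly
#' uniform under the null, used for calibration checks). Pathways without
#' background hits are excluded and listed in attribute `"excluded"`.
#'
#' @param sig_features,background_features Tibbles with `feature_id`, `mz`
#'   (significant list must be a subset of the background).
#' @param db A `pathway_db`.
#' @param adducts,ppm_tol Passed to [annotate_mz()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param tie_break `"conservative"` (default) or `"randomized"`.
#' @return An `enrichment_table` tibble per pathway: hits, size, annotated
#'   background hits, `fold_enrichment`, `log2_fold_enrichment`,
#'   `p_mummichog`.
#' @export
mummichog_enrichment <- function(sig_features, background_features, db,
                                 adducts = "M+H", ppm_tol = 2, n_perm = 200,
                                 seed = 1L,
                                 tie_break = c("conservative", "randomized")) {
  tie_break <- match.arg(tie_break)
  stopifnot(n_perm >= 100)
  if (!all(sig_features$feature_id %in% background_features$feature_id)) {
    stop("significant features must be a subset of the background", call. = FALSE)
  }
  memb <- pathway_members(db)
  ann_bg <- annotate_mz(background_features, db, adducts, ppm_tol)
  bg_cpds <- unique(ann_bg$compound_id)
  N <- length(bg_cpds)
  pw <- pathway_hits(bg_cpds, memb) |> rename(bg_hits = "hits")
  excluded <- setdiff(db$pathways$pathway_id, pw$pathway_id)
  if (nrow(pw) == 0) stop("no pathway has background hits", call. = FALSE)
  sizes <- memb |> dplyr::count(.data$pathway_id, name = "size")

  cpds_of <- function(feature_ids) {
    unique(ann_bg$compound_id[ann_bg$feature_id %in% feature_ids])
  }
  stat_for <- function(feature_ids) {
    cp <- cpds_of(feature_ids)
    n_ann <- length(cp)
    hits <- pathway_hits(cp, memb)
    h <- setNames(rep(0L, nrow(pw)), pw$pathway_id)
    h[hits$pathway_id[hits$pathway_id %in% names(h)]] <-
      hits$hits[hits$pathway_id %in% names(h)]
    # -log hypergeometric upper tail: larger = more enriched
    s <- -hypergeom_tail(h, pw$bg_hits, N, n_ann, log.p = TRUE)
    list(stat = s, hits = h, n_ann = n_ann)
  }

  obs <- stat_for(sig_features$feature_id)
  n_sig <- nrow(sig_features)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      draw <- sample(background_features$feature_id, n_sig)
      stat_for(draw)$stat
    }, numeric(nrow(pw)))
  })
  if (nrow(pw) == 1) null_stats <- matrix(null_stats, nrow = 1)
  p <- with_seed(seed + 1L, {
    vapply(seq_len(nrow(pw)), function(i) {
      greater <- sum(null_stats[i, ] > obs$stat[i] + 1e-12)
      ties <- sum(abs(null_stats[i, ] - obs$stat[i]) <= 1e-12)
      if (tie_break == "conservative") {
        (1 + greater + ties) / (1 + n_perm)
      } else {
        (runif(1) * (1 + ties) + greater) / (1 + n_perm)
      }
    }, numeric(1))
  })
  fe <- (obs$hits / max(obs$n_ann, 1)) / (pw$bg_hits / N)
  res <- tibble(
    pathway_id = pw$pathway_id,
    hits = as.integer(obs$hits),
    size = sizes$size[match(pw$pathway_id, sizes$pathway_id)],
    bg_hits = pw$bg_hits,
    fold_enrichment = fe,
    log2_fold_enrichment = ifelse(fe > 0, log2(fe), NA_real_),
    p_mummichog = p
  )
  attr(res, "excluded") <- excluded
  attr(res, "n_sig_annotated") <- obs$n_ann
  res
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(in_set, scores, weight) {
  w <- abs(scores)^weight
  w[!in_set] <- 0
  nr <- sum(w)
  miss <- sum(!in_set)
  if (nr == 0 || miss == 0) return(0)
  run <- cumsum(ifelse(in_set, w / nr, -1 / miss))
  run[which.max(abs(run))]
}

#' GSEA-style enrichment on a ranked feature list
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment per pathway on features
#' ranked by a signed score (e.g. the Welch t statistic), null by
#' feature-label permutation; two-sided p on the normalised enrichment score
#' with the +1 correction. Pathways with fewer than 2 annotated features are
#' excluded.
#'
#' @param scores Named numeric vector: signed ranking score per feature id.
#' @param annotation Tibble `feature_id`, `compound_id` (from
#'   [annotate_mz()]) linking features to pathway compounds.
#' @param db A `pathway_db`.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param weight KS weight exponent (>= 0); 0 gives the classic unweighted
#'   statistic.
#' @return Tibble per pathway: `pathway_id`, `n_members`, `es`, `nes`,
#'   `p_gsea`.
#' @export
gsea_enrichment <- function(scores, annotation, db, n_perm = 200, seed = 1L,
                            weight = 1) {
  stopifnot(weight >= 0, !is.null(names(scores)))
  memb <- pathway_members(db)
  feat2pw <- annotation |>
    dplyr::inner_join(memb, by = "compound_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$feature_id, .data$pathway_id)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  ids <- names(s)
  n <- length(s)
  out <- list()
  perm_sets <- NULL
  for (pwid in sort(unique(feat2pw$pathway_id))) {
    members <- feat2pw$feature_id[feat2pw$pathway_id == pwid]
    in_set <- ids %in% members
    m <- sum(in_set)
    if (m < 2 || m >= n) next
    es <- gsea_es(in_set, s, weight)
    null_es <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        gsea_es(seq_len(n) %in% sample(n, m), s, weight)
      }, numeric(1))
    })
    denom <- mean(abs(null_es))
    nes <- if (denom > 0) es / denom else 0
    nes_null <- if (denom > 0) null_es / denom else null_es
    p <- (1 + sum(abs(nes_null) >= abs(nes))) / (1 + n_perm)
    out[[pwid]] <- tibble(pathway_id = pwid, n_members = m, es = es,
                          nes = nes, p_gsea = p)
  }
  if (length(out) == 0) {
    return(tibble(pathway_id = character(), n_members = integer(),
                  es = numeric(), nes = numeric(), p_gsea = numeric()))
  }
  bind_rows(out)
}

#' Select pathways significant under both enrichment algorithms
#'
#' The dual-significance rule: a pathway is selected iff its accurate-mass
#' permutation p AND its GSEA p are both strictly below `alpha` (the
#' "top-right quadrant" of the p-value scatter).
#'
#' @param enrichment Tibble with `pathway_id`, `p_mummichog`, `p_gsea`
#'   (e.g. the join of [mummichog_enrichment()] and [gsea_enrichment()]).
#' @param alpha Significance level (default 0.05, strict inequality).
#' @return The input with a logical `selected` column.
#' @export
select_enriched <- function(enrichment, alpha = 0.05) {
  stopifnot(all(c("p_mummichog", "p_gsea") %in% names(enrichment)))
  mutate(enrichment,
         selected = .data$p_mummichog < alpha & .data$p_gsea < alpha)
}

#' Dual p-value enrichment scatter
#'
#' Scatter of the two enrichment p-values per pathway (-log10 scales), point
#' size by absolute log2 fold enrichment, with the `alpha` significance
#' boxes; selected pathways sit in the top-right quadrant.
#'
#' @param object Output of [select_enriched()].
#' @param alpha Significance level drawn as dashed lines.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.enrichment_table <- function(object, alpha = 0.05, ...) {
  df <- mutate(as_tibble(object),
               size = abs(.data$log2_fold_enrichment %||% 1))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_mummichog),
                                   -log10(.data$p_gsea))) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(size = .data$size), alpha = 0.7) +
    ggplot2::labs(x = "-log10 p (accurate-mass permutation)",
                  y = "-log10 p (GSEA)",
                  size = "|log2 fold enrichment|") +
    ggplot2::theme_minimal()
}

#' Youden-optimal threshold on a score
#'
#' Scans the midpoints of sorted unique scores and returns the threshold
#' maximising J = sensitivity + specificity - 1 (classification rule:
#' positive iff score > threshold). Ties resolve to the lowest threshold.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical labels.
#' @return List with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), any(positive), any(!positive))
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- list(cutoff = cand[1], j = -Inf, sensitivity = NA, specificity = NA)
  for (ct in cand) {
    pred <- scores > ct
    sens <- sum(pred & positive) / sum(positive)
    spec <- sum(!pred & !positive) / sum(!positive)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) {
      best <- list(cutoff = ct, j = j, sensitivity = sens, specificity = spec)
    }
  }
  best
}

#' Fit the PC1/Youden outcome-score model
#'
#' Standardises the member features (significant metabolites from the
#' enriched pathways) by training mean/SD, takes the first principal
#' component of the covariance as the score direction (sign fixed so the
#' largest-|loading| member is positive), orients the score so the positive
#' class has the higher mean, and places the classification cutoff at
#' Youden's J optimum over the training scores.
#'
#' @param X Numeric matrix (training measurements x member features, >= 2
#'   features).
#' @param positive Logical training labels (both classes present).
#' @return An `outcome_score_model`.
#' @export
fit_outcome_score <- function(X, positive) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 member features", call. = FALSE)
  stopifnot(nrow(X) == length(positive), any(positive), any(!positive))
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  if (any(scale == 0)) stop("member feature(s) with zero variance", call. = FALSE)
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  eg <- eigen(stats::cov(Xs), symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  scores <- as.numeric(Xs %*% v)
  orientation <- if (mean(scores[positive]) >= mean(scores[!positive])) 1 else -1
  yc <- youden_cutoff(scores * orientation, positive)
  structure(
    list(features = colnames(X) %||% sprintf("F%03d", seq_len(ncol(X))),
         center = center, scale = scale, loadings = setNames(v, colnames(X)),
         explained_var = eg$values[1] / sum(pmax(eg$values, 0)),
         orientation = orientation, cutoff = yc$cutoff, youden_j = yc$j,
         sensitivity = yc$sensitivity, specificity = yc$specificity,
         train_scores = scores, train_positive = positive),
    class = "outcome_score_model"
  )
}

#' Score and classify new measurements
#'
#' Projects new data (standardised with the *training* parameters) on the
#' stored PC1 direction and classifies by the stored Youden cutoff and
#' orientation.
#'
#' @param object An `outcome_score_model`.
#' @param newdata Matrix or data frame carrying the model's member features
#'   (error listing ids if any are missing).
#' @param ... Ignored.
#' @return Tibble: `score`, `predicted_positive`.
#' @export
predict.outcome_score_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop("missing member feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- newdata[, object$features, drop = FALSE]
  if (!is.null(object$pre_log2_impute)) {
    imp <- object$pre_log2_impute[object$features]
    zero <- X == 0
    X[zero] <- matrix(imp, nrow(X), ncol(X), byrow = TRUE)[zero]
    X <- log2(X)
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  score <- as.numeric(Xs %*% object$loadings)
  tibble(score = score,
         predicted_positive = score * object$orientation > object$cutoff)
}

#' @export
print.outcome_score_model <- function(x, ...) {
  cat(sprintf("<outcome_score_model> %d member features; PC1 explains %.1f%%; J = %.2f at cutoff %.3g\n",
              length(x$features), 100 * x$explained_var, x$youden_j,
              x$cutoff * x$orientation))
  invisible(x)
}

#' @export
tidy.outcome_score_model <- function(x, ...) {
  tibble(feature_id = x$features, loading = unname(x$loadings))
}

#' @export
glance.outcome_score_model <- function(x, ...) {
  tibble(n_features = length(x$features), explained_var = x$explained_var,
         cutoff = x$cutoff, orientation = x$orientation,
         youden_j = x$youden_j, sensitivity = x$sensitivity,
         specificity = x$specificity)
}

#' Density plot of outcome scores by class
#'
#' @param object An `outcome_score_model`.
#' @param ... Ignored.
#' @return A ggplot of the training-score densities with the Youden cutoff.
#' @export
autoplot.outcome_score_model <- function(object, ...) {
  df <- tibble(score = object$train_scores * object$orientation,
               class = ifelse(object$train_positive, "II/III", "I"))
  ggplot2::ggplot(df, ggplot2::aes(.data$score, fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_rug(ggplot2::aes(colour = .data$class)) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "PC1 score (oriented)", y = "density") +
    ggplot2::theme_minimal()
}

#' Balanced accuracy of a binary prediction
#'
#' @param predicted,actual Logical vectors.
#' @return Mean of sensitivity and specificity.
#' @export
balanced_accuracy <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  sens <- sum(predicted & actual) / sum(actual)
  spec <- sum(!predicted & !actual) / sum(!actual)
  (sens + spec) / 2
}

#' End-to-end outcome branch on a feature table
#'
#' Chains the endogenous filter, Welch/BH differential testing, dual pathway
#' enrichment, pathway selection and the PC1/Youden model for one outcome
#' axis. Member features for the score are those BH-significant at
#' `q_gate` AND annotated to a selected pathway.
#'
#' @param ft A [feature_table] (training measurements).
#' @param outcome `"side_effects"`, `"response"` or `"eeg"`.
#' @param db A `pathway_db`.
#' @param min_presence,min_cv Endogenous filter thresholds.
#' @param q_gate BH q-value gate defining the significant-metabolite list
#'   (default 0.25).
#' @param alpha Dual-enrichment significance level.
#' @param n_perm,seed Permutation settings.
#' @param log_transform Run the differential test and the score model on
#'   log2-transformed intensities (zeros imputed at half the feature's
#'   minimum positive value). The default analyses raw intensities, matching
#'   the source workflow; the log option is provided for data with heavier
#'   multiplicative noise.
#' @return List: `differential`, `enrichment` (with `selected`), `model`
#'   (NULL if fewer than 2 member features), `members`.
#' @export
outcome_workflow <- function(ft, outcome = c("side_effects", "response", "eeg"),
                             db, min_presence = 0.5, min_cv = 0.3,
                             q_gate = 0.25, alpha = 0.05, n_perm = 200,
                             seed = 1L, log_transform = FALSE) {
  outcome <- match.arg(outcome)
  cls <- switch(outcome, side_effects = ft$row_data$side_effects_class,
                response = ft$row_data$response_class,
                eeg = ft$row_data$eeg_class)
  positive <- outcome_positive(cls)
  sub <- filter_endogenous(ft, min_presence, min_cv)
  # zeros (feature absent) are imputed at half the feature's minimum positive
  # value before the log, the usual metabolomics convention
  impute <- apply(sub$nauc, 2, function(x) {
    p <- x[x > 0]
    if (length(p)) min(p) / 2 else 1
  })
  xform <- if (log_transform) {
    function(x) {
      imp <- impute[colnames(x)]
      zero <- x == 0
      x[zero] <- matrix(imp, nrow(x), ncol(x), byrow = TRUE)[zero]
      log2(x)
    }
  } else identity
  diff <- differential_abundance(xform(sub$nauc), positive,
                                 values = if (log_transform) "log2" else "raw")
  sig <- diff$feature_id[diff$q <= q_gate]
  bg_feats <- select(sub$col_data, "feature_id", "mz")
  sig_feats <- bg_feats[bg_feats$feature_id %in% sig, ]
  ann <- annotate_mz(bg_feats, db)
  mm <- mummichog_enrichment(sig_feats, bg_feats, db, n_perm = n_perm,
                             seed = seed)
  gs <- gsea_enrichment(setNames(diff$t, diff$feature_id), ann, db,
                        n_perm = n_perm, seed = seed + 1L)
  enr <- select_enriched(
    dplyr::inner_join(mm, gs, by = "pathway_id"), alpha)
  class(enr) <- c("enrichment_table", class(enr))
  sel_pw <- enr$pathway_id[enr$selected]
  memb <- pathway_members(db)
  sel_cpds <- memb$compound_id[memb$pathway_id %in% sel_pw]
  member_feats <- intersect(sig, ann$feature_id[ann$compound_id %in% sel_cpds])
  model <- if (length(member_feats) >= 2) {
    m <- fit_outcome_score(xform(sub$nauc[, member_feats, drop = FALSE]),
                           positive)
    if (log_transform) m$pre_log2_impute <- impute[member_feats]
    m
  }
  list(outcome = outcome, differential = diff, enrichment = enr,
       members = member_feats, model = model, positive = positive)
}
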