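# Dual predictor-importance ranking for the serum-VPA regression:
# RReliefF and bagged-forest permutation importance, combined into one
# normalised weight with an empirical selection cutoff.

#' Filter drug-related features by presence among VPA measurements
#'
#' Keeps features present in at least `min_presence` of the measurements in
#' which the patient was receiving VPA (presence elsewhere is irrelevant).
#'
#' @param ft A [feature_table].
#' @param min_presence Presence fraction threshold (default 0.8).
#' @param on_vpa Logical per-measurement flag; defaults to
#'   `total_vpa_mgL > 0` from the row metadata.
#' @return The filtered `feature_table`.
#' @export
filter_drug_features <- function(ft, min_presence = 0.8, on_vpa = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(on_vpa)) on_vpa <- ft$row_data$total_vpa_mgL > 0
  if (!any(on_vpa)) stop("no VPA measurements", call. = FALSE)
  keep <- presence_fraction(ft, rows = on_vpa) >= min_presence
  ft[, keep]
}

#' RReliefF feature weights for a continuous target
#'
#' Regression ReliefF (the difference-of-probabilities estimate over k
#' nearest neighbours with rank-decayed influence): features are scaled to
#' [0, 1], neighbours found by Manhattan distance, and each feature weighted
#' by how much its differences track target differences among neighbours.
#' Deterministic given the seed (and fully deterministic when all instances
#' are sampled, the default).
#'
#' @param X Numeric matrix (observations x features), no missing values.
#' @param y Continuous target (e.g. total serum VPA, mg/L).
#' @param k_neighbors Neighbours per sampled instance; must be < `nrow(X)`.
#' @param n_sampled Number of instances to sample (all, by default).
#' @param sigma Rank-decay scale of neighbour influence.
#' @param seed Seed for the instance sample (ignored when all are used).
#' @return Named numeric vector of weights, one per feature (range [-1, 1]).
#' @export
rrelieff_weights <- function(X, y, k_neighbors = 10, n_sampled = nrow(X),
                             sigma = 20, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(!anyNA(X), !anyNA(y), nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (k_neighbors >= n) stop("k_neighbors must be < nrow(X)", call. = FALSE)
  w <- setNames(numeric(p), colnames(X))
  ry <- diff(range(y))
  if (ry == 0) return(w)
  rng <- apply(X, 2, function(col) {
    r <- diff(range(col)); if (r == 0) 1 else r
  })
  Xs <- sweep(X, 2, apply(X, 2, min), "-")
  Xs <- sweep(Xs, 2, rng, "/")
  idx <- if (n_sampled >= n) seq_len(n) else
    with_seed(seed, sort(sample(n, n_sampled)))
  infl <- exp(-(seq_len(k_neighbors) / sigma)^2)
  infl <- infl / sum(infl)
  NdY <- 0; NdF <- numeric(p); NdYdF <- numeric(p)
  for (i in idx) {
    d <- colSums(abs(t(Xs) - Xs[i, ]))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k_neighbors)] # stable tie-break
    dy <- abs(y[nb] - y[i]) / ry
    dF <- abs(Xs[nb, , drop = FALSE] -
                matrix(Xs[i, ], k_neighbors, p, byrow = TRUE))
    NdY <- NdY + sum(infl * dy)
    NdF <- NdF + colSums(infl * dF)
    NdYdF <- NdYdF + colSums(infl * dy * dF)
  }
  m <- length(idx)
  if (NdY <= 0 || m - NdY <= 0) return(w)
  w[] <- NdYdF / NdY - (NdF - NdYdF) / (m - NdY)
  w
}

#' Bagged-forest permutation importance
#'
#' Out-of-bag permutation importance from a bagged regression forest
#' (all features tried at each split, i.e. bagging rather than a random
#' subspace), deterministic given the seed.
#'
#' @param X Numeric matrix (observations x features).
#' @param y Continuous target.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return Named numeric vector of importances.
#' @export
forest_importance <- function(X, y, n_trees = 300, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  df <- as.data.frame(X)
  if (is.null(colnames(X))) names(df) <- paste0("V", seq_len(ncol(X)))
  df$.y <- y
  if (var(y) == 0) {
    return(setNames(numeric(ncol(X)), setdiff(names(df), ".y")))
  }
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df, num.trees = n_trees,
    mtry = ncol(X), importance = "permutation", seed = seed,
    num.threads = 1
  )
  fit$variable.importance
}

#' Combine RReliefF and forest importances and select predictors
#'
#' Each weight vector is min-max scaled to [0, 1] (an all-equal vector
#' contributes 0.5 uniformly), the two are combined (arithmetic mean by
#' default), and the combination is renormalised so its maximum is 1.
#' A predictor is selected iff its combined weight is strictly above the
#' cutoff (default: the empirical 0.1).
#'
#' @param relief_w,forest_w Equal-length finite weight vectors.
#' @param cutoff Selection cutoff on the combined weight.
#' @param method Combination strategy: `"mean"`, `"max"` or `"rank-mean"`.
#' @return An `importance_report` tibble: `feature_id`, `relief_weight`,
#'   `forest_weight`, `combined_weight`, `selected`.
#' @export
combine_and_select <- function(relief_w, forest_w, cutoff = 0.1,
                               method = c("mean", "max", "rank-mean")) {
  method <- match.arg(method)
  stopifnot(length(relief_w) == length(forest_w))
  assert_finite(relief_w, "relief_w"); assert_finite(forest_w, "forest_w")
  ids <- names(relief_w) %||% names(forest_w) %||%
    sprintf("F%03d", seq_along(relief_w))
  r <- minmax_scale(relief_w); f <- minmax_scale(forest_w)
  combined <- switch(method,
    mean = (r + f) / 2,
    max = pmax(r, f),
    `rank-mean` = minmax_scale((rank(r) + rank(f)) / 2)
  )
  if (max(combined) > 0) combined <- combined / max(combined)
  structure(
    tibble(feature_id = ids, relief_weight = unname(r),
           forest_weight = unname(f), combined_weight = unname(combined),
           selected = unname(combined > cutoff)),
    class = c("importance_report", "tbl_df", "tbl", "data.frame"),
    cutoff = cutoff, method = method
  )
}

#' @export
tidy.importance_report <- function(x, ...) as_tibble(x)

#' Plot an importance report
#'
#' Lollipop plot of the combined normalised weight per predictor with the
#' selection cutoff as a dashed line.
#'
#' @param object An `importance_report`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.importance_report <- function(object, ...) {
  cutoff <- attr(object, "cutoff") %||% 0.1
  df <- arrange(as_tibble(object), dplyr::desc(.data$combined_weight)) |>
    mutate(feature_id = factor(.data$feature_id, levels = .data$feature_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_id, .data$combined_weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature_id, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "combined normalised weight",
                  colour = "selected") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
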