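# Gaussian-process regression with an exponential (Ornstein-Uhlenbeck)
# covariance kernel, the serum-concentration model of the pipeline.

#' Exponential covariance kernel
#'
#' `k(x, x') = sigma_f2 * exp(-||x - x'|| / length_scale)`.
#'
#' @param D Matrix of Euclidean distances.
#' @param sigma_f2 Kernel amplitude (> 0).
#' @param length_scale Length scale (> 0).
#' @return Covariance matrix of the same shape as `D`.
#' @export
exp_kernel <- function(D, sigma_f2, length_scale) {
  sigma_f2 * exp(-D / length_scale)
}

egpr_nll <- function(theta, D, y, jitter) {
  sf2 <- exp(theta[1]); ell <- exp(theta[2]); sn2 <- exp(theta[3])
  n <- length(y)
  K <- exp_kernel(D, sf2, ell) + diag(sn2 + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    for (j in 10^seq(-9, -6)) {
      L <- tryCatch(chol(K + diag(j, n)), error = function(e) NULL)
      if (!is.null(L)) break
    }
    if (is.null(L)) return(1e10)
  }
  a <- backsolve(L, forwardsolve(t(L), y))
  0.5 * sum(y * a) + sum(log(diag(L))) + n / 2 * log(2 * pi)
}

#' Fit an exponential-kernel Gaussian-process regression (eGPR)
#'
#' Inputs are standardised by training statistics; hyperparameters (kernel
#' amplitude, length scale, noise variance) are chosen by marginal-likelihood
#' maximisation with seeded multi-start, on a jitter ladder for numerical
#' stability. Pass `hyper` to skip optimisation (e.g. a near-zero noise
#' variance for exact interpolation).
#'
#' @param X Numeric matrix of predictors (observations x features).
#' @param y Numeric targets (mg/L for serum concentrations).
#' @param restarts Number of random restarts of the optimiser.
#' @param seed Seed for the restarts.
#' @param hyper Optional list with `sigma_f2`, `length_scale`, `sigma_n2`
#'   fixing the hyperparameters.
#' @param jitter Base diagonal jitter (escalated up to 1e-6 if the
#'   covariance is numerically non-positive-definite).
#' @return An `egpr_model`.
#' @export
fit_egpr <- function(X, y, restarts = 8, seed = 1L, hyper = NULL,
                     jitter = 1e-10) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  center <- colMeans(X)
  scale <- apply(X, 2, sd); scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  y_mean <- mean(y)
  r <- y - y_mean
  D <- as.matrix(dist(Xs))
  if (is.null(hyper)) {
    med <- median(D[upper.tri(D)])
    if (!is.finite(med) || med <= 0) med <- 1
    sdy <- max(sd(y), 1e-6)
    starts <- with_seed(seed, {
      lapply(seq_len(max(restarts, 1)), function(i) {
        c(log(sdy^2 * runif(1, 0.3, 3)),
          log(med * exp(runif(1, log(0.25), log(4)))),
          log(sdy^2 * runif(1, 0.005, 0.3)))
      })
    })
    fits <- lapply(starts, function(th0) {
      tryCatch(optim(th0, egpr_nll, D = D, y = r, jitter = jitter,
                     method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-9)),
               error = function(e) list(value = Inf))
    })
    best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
    if (!is.finite(best$value)) stop("eGPR optimisation failed", call. = FALSE)
    th <- best$par
    hyper <- list(sigma_f2 = exp(th[1]), length_scale = exp(th[2]),
                  sigma_n2 = exp(th[3]))
    nll <- best$value
  } else {
    stopifnot(all(c("sigma_f2", "length_scale", "sigma_n2") %in% names(hyper)))
    nll <- egpr_nll(log(c(hyper$sigma_f2, hyper$length_scale,
                          pmax(hyper$sigma_n2, 1e-300))), D, r, jitter)
  }
  n <- length(y)
  K <- exp_kernel(D, hyper$sigma_f2, hyper$length_scale) +
    diag(hyper$sigma_n2 + jitter, n)
  L <- NULL
  for (j in c(0, 10^seq(-10, -6))) {
    L <- tryCatch(chol(K + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) {
    stop("covariance matrix not positive definite after jitter escalation",
         call. = FALSE)
  }
  alpha <- backsolve(L, forwardsolve(t(L), r))
  structure(
    list(X_train = Xs, center = center, scale = scale, y_mean = y_mean,
         hyper = hyper, alpha = alpha, L = L, loglik = -nll, n = n,
         p = ncol(X)),
    class = "egpr_model"
  )
}

#' Predict serum concentrations from an eGPR model
#'
#' Posterior-mean predictions; negative values are clipped to 0 mg/L since
#' concentrations cannot be negative.
#'
#' @param object An `egpr_model`.
#' @param newdata Matrix with the training columns.
#' @param clip_negative Clip negative posterior means at 0.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.egpr_model <- function(object, newdata, clip_negative = TRUE, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  Ks <- exp_kernel(cross_dist(Xs, object$X_train),
                   object$hyper$sigma_f2, object$hyper$length_scale)
  pred <- as.numeric(Ks %*% object$alpha) + object$y_mean
  if (clip_negative) pred <- pmax(pred, 0)
  pred
}

#' @export
print.egpr_model <- function(x, ...) {
  cat(sprintf("<egpr_model> n = %d, p = %d; sigma_f2 = %.3g, length_scale = %.3g, sigma_n2 = %.3g\n",
              x$n, x$p, x$hyper$sigma_f2, x$hyper$length_scale, x$hyper$sigma_n2))
  invisible(x)
}

#' @export
tidy.egpr_model <- function(x, ...) {
  tibble(term = c("sigma_f2", "length_scale", "sigma_n2"),
         estimate = c(x$hyper$sigma_f2, x$hyper$length_scale, x$hyper$sigma_n2))
}

#' @export
glance.egpr_model <- function(x, ...) {
  tibble(n = x$n, p = x$p, log_marginal_likelihood = x$loglik)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurement series with the identity line:
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with population
#' (1/n) moments. Conventions for degenerate input: both series constant
#' with equal means gives 1; exactly one constant series gives 0.
#'
#' @param actual,predicted Equal-length finite numeric vectors (n >= 2).
#' @return A one-row `concordance_result` tibble: `ccc`, `pearson_r`,
#'   `location_shift`, `scale_ratio`, `n`.
#' @export
lin_ccc <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  assert_finite(actual, "actual"); assert_finite(predicted, "predicted")
  n <- length(actual)
  mx <- mean(actual); my <- mean(predicted)
  sx2 <- mean((actual - mx)^2); sy2 <- mean((predicted - my)^2)
  sxy <- mean((actual - mx) * (predicted - my))
  if (sx2 == 0 && sy2 == 0) {
    ccc <- if (mx == my) 1 else 0
    r <- ccc
  } else if (sx2 == 0 || sy2 == 0) {
    ccc <- 0; r <- 0
  } else {
    ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
    r <- sxy / sqrt(sx2 * sy2)
  }
  structure(
    tibble(ccc = ccc, pearson_r = r, location_shift = mx - my,
           scale_ratio = if (sy2 > 0) sqrt(sx2 / sy2) else NA_real_, n = n),
    class = c("concordance_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Screen regression model families by cross-validated concordance
#'
#' Runs seeded k-fold cross-validation for each registered model family and
#' ranks them by mean CV concordance (Lin's CCC) with RMSE alongside. The
#' default registry holds the exponential-kernel GP (mandatory), a linear
#' ridge comparator and bagged regression trees.
#'
#' @param X Predictor matrix.
#' @param y Targets.
#' @param folds Number of CV folds (must be <= `nrow(X)`).
#' @param seeds Integer vector; one CV replicate per seed.
#' @param families Named list of families, each `list(fit = function(X, y),
#'   predict = function(model, X))`.
#' @return Tibble per family: mean/SD of CV CCC and RMSE, ranked by CCC.
#' @export
screen_regressors <- function(X, y, folds = 5, seeds = 1:3,
                              families = default_regressor_families()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds > n) stop("folds must be <= number of observations", call. = FALSE)
  stopifnot(length(families) >= 1, !is.null(names(families)))
  res <- list()
  for (fam in names(families)) {
    f <- families[[fam]]
    ccc_s <- rmse_s <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      fold_id <- with_seed(seeds[si], sample(rep_len(seq_len(folds), n)))
      pred <- numeric(n)
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        fit <- f$fit(X[tr, , drop = FALSE], y[tr])
        pred[!tr] <- f$predict(fit, X[!tr, , drop = FALSE])
      }
      ccc_s[si] <- lin_ccc(y, pred)$ccc
      rmse_s[si] <- sqrt(mean((y - pred)^2))
    }
    res[[fam]] <- tibble(
      family = fam, mean_ccc = mean(ccc_s), sd_ccc = sd(ccc_s),
      mean_rmse = mean(rmse_s), sd_rmse = sd(rmse_s), n_seeds = length(seeds)
    )
  }
  arrange(bind_rows(res), dplyr::desc(.data$mean_ccc))
}

#' @rdname screen_regressors
#' @export
default_regressor_families <- function() {
  list(
    egpr = list(
      fit = function(X, y) fit_egpr(X, y, restarts = 4),
      predict = function(m, X) predict(m, X)
    ),
    ridge = list(
      fit = function(X, y) {
        glmnet::cv.glmnet(X, y, alpha = 0, nfolds = 5)
      },
      predict = function(m, X) as.numeric(predict(m, X, s = "lambda.min"))
    ),
    bagged_trees = list(
      fit = function(X, y) {
        df <- as.data.frame(X); df$.y <- y
        ranger::ranger(dependent.variable.name = ".y", data = df,
                       num.trees = 300, mtry = ncol(X), seed = 1,
                       num.threads = 1)
      },
      predict = function(m, X) {
        predict(m, data = as.data.frame(X), num.threads = 1)$predictions
      }
    )
  )
}

#' Per-measurement ratio of two feature signals
#'
#' Ratio of mean nAUCs of a numerator and denominator feature (e.g.
#' 3-heptanone over 4-OH-gamma-lactone, a proxy for the relative activity of
#' the beta- vs omega-1-oxidation routes). Missing when the denominator is 0.
#'
#' @param ft A [feature_table].
#' @param numerator_feature,denominator_feature Feature ids present in `ft`.
#' @return Tibble per measurement: `measurement_id`, `subject_id`, `ratio`.
#' @seealso [subject_ratio_summary()]
#' @export
pathway_activity_ratio <- function(ft, numerator_feature, denominator_feature) {
  stopifnot(inherits(ft, "feature_table"))
  miss <- setdiff(c(numerator_feature, denominator_feature),
                  colnames(ft$nauc))
  if (length(miss)) stop("features not in table: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  num <- ft$nauc[, numerator_feature]
  den <- ft$nauc[, denominator_feature]
  tibble(
    measurement_id = rownames(ft$nauc),
    subject_id = ft$row_data$subject_id,
    ratio = unname(ifelse(den > 0, num / den, NA_real_))
  )
}

#' Per-subject summary of a pathway-activity ratio
#'
#' Median and IQR of the per-measurement ratio across each subject's visits;
#' missing ratios (zero denominator) are excluded.
#'
#' @param ratios Output of [pathway_activity_ratio()].
#' @return Tibble per subject: `subject_id`, `n`, `median_ratio`, `iqr_ratio`.
#' @export
subject_ratio_summary <- function(ratios) {
  ratios |>
    filter(!is.na(.data$ratio)) |>
    group_by(.data$subject_id) |>
    summarise(n = dplyr::n(), median_ratio = median(.data$ratio),
              iqr_ratio = stats::IQR(.data$ratio), .groups = "drop")
}

#' Scatter of actual vs predicted concentrations
#'
#' @param data Data frame with columns `actual` and `predicted` (mg/L).
#' @param therapeutic_range Optional `c(lower, upper)` band to shade.
#' @return A ggplot with the identity line.
#' @export
plot_concordance <- function(data, therapeutic_range = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$actual, .data$predicted))
  if (!is.null(therapeutic_range)) {
    p <- p + ggplot2::annotate("rect", xmin = therapeutic_range[1],
                               xmax = therapeutic_range[2], ymin = -Inf,
                               ymax = Inf, alpha = 0.15, fill = "grey50")
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "actual serum concentration (mg/L)",
                  y = "predicted serum concentration (mg/L)") +
    ggplot2::theme_minimal()
}
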