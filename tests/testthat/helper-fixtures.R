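# Shared fixtures, built once per test run, and small independent oracles.

# scan-level cohort: 6 subjects x 2 visits, modest feature set
tiny_cfg <- cohort_config(
  n_subjects = 6, visits_per_subject = 2, n_endogenous_features = 15,
  n_nuisance_features = 15, seed = 42
)
tiny_sim <- simulate_cohort(tiny_cfg)

# noise-free cohort for exactness checks (single batch, no mass jitter)
clean_cfg <- cohort_config(
  n_subjects = 4, visits_per_subject = 2, n_endogenous_features = 8,
  n_nuisance_features = 6, noise_cv = 0, mz_jitter_ppm = 0,
  n_batches = 1, batch_scale_sd = 0, seed = 7
)
clean_sim <- simulate_cohort(clean_cfg)

# study-scale feature-level matrix (75 x 111)
fm_default <- simulate_feature_matrix(cohort_config(seed = 101))

# a hand-made feature table for filter arithmetic
make_ft <- function(nauc, total_vpa = NULL, batch = NULL, subject = NULL,
                    classes = NULL) {
  n <- nrow(nauc); p <- ncol(nauc)
  if (is.null(colnames(nauc))) colnames(nauc) <- sprintf("F%03d", seq_len(p))
  rn <- sprintf("M%03d", seq_len(n))
  rownames(nauc) <- rn
  rd <- tibble::tibble(
    measurement_id = rn,
    subject_id = if (is.null(subject)) sprintf("S%02d", seq_len(n)) else subject,
    cohort = "paediatric",
    batch = if (is.null(batch)) "B1" else batch,
    total_vpa_mgL = if (is.null(total_vpa)) rep(0, n) else total_vpa,
    free_vpa_mgL = if (is.null(total_vpa)) rep(0, n) else total_vpa * 0.1
  )
  if (!is.null(classes)) rd <- dplyr::bind_cols(rd, classes)
  new_feature_table(
    nauc = nauc, presence = nauc > 0, row_data = rd,
    col_data = tibble::tibble(feature_id = colnames(nauc),
                              mz = 100 + seq_len(p), polarity = "+",
                              tol_ppm = 5)
  )
}

# independent trapezoid + mean oracle for nAUC
nauc_oracle <- function(trace, scan_times, windows) {
  per <- sapply(seq_len(nrow(windows)), function(k) {
    a <- windows$start_s[k]; b <- windows$end_s[k]
    grid <- sort(unique(c(a, b, scan_times[scan_times > a & scan_times < b])))
    y <- stats::approx(scan_times, trace, xout = grid, rule = 2)$y
    sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2) / (b - a)
  })
  mean(per)
}

# independent Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# direct-formula oracle for Lin's concordance (population moments)
ccc_oracle <- function(x, y) {
  n <- length(x)
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# brute-force Youden scan over the midpoint candidate grid
youden_oracle <- function(scores, positive) {
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- -Inf
  for (ct in cand) {
    pred <- scores > ct
    j <- sum(pred & positive) / sum(positive) +
      sum(!pred & !positive) / sum(!positive) - 1
    if (j > best) best <- j
  }
  best
}

# exhaustive enumeration of the hypergeometric upper tail: probability that a
# random n-subset of a background of size N (K in the pathway) has >= k hits
hypergeom_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k) # first K background indices are the pathway
}

# balanced train/test split of measurement indices by subject
split_by_subject <- function(subject_id, frac = 2 / 3, seed = 1) {
  subj <- unique(subject_id)
  tr <- withr::with_seed(seed, sample(subj, ceiling(frac * length(subj))))
  subject_id %in% tr
}
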