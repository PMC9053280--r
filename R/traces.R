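# Raw time-resolved spectra -> measurements x features mean-nAUC matrix:
# exhalation detection, spectral alignment, KDE feature consolidation,
# presence + breath-correlation filters, nAUC integration.

#' Detect exhalation windows in a TIC trace
#'
#' Maximal runs of scans where the TIC exceeds
#' `baseline + threshold_frac * (max - baseline)`, with the baseline taken as
#' the lower-decile TIC. Runs separated by less than `min_gap_s` are merged,
#' then runs shorter than `min_duration_s` are dropped. A flat TIC yields no
#' windows (not an error); measurements with fewer than two windows are
#' flagged as failed downstream.
#'
#' @param tic Per-scan total ion current (finite, >= 10 scans).
#' @param scan_times Scan times (s), strictly increasing, same length.
#' @param threshold_frac Relative threshold between baseline and maximum.
#' @param min_duration_s Minimum window duration (s).
#' @param min_gap_s Windows closer than this are merged (s).
#' @return Tibble of ordered, non-overlapping windows (`start_s`, `end_s`).
#' @export
detect_exhalations <- function(tic, scan_times, threshold_frac = 0.3,
                               min_duration_s = 5, min_gap_s = 3) {
  assert_finite(tic, "tic")
  stopifnot(length(tic) == length(scan_times), length(tic) >= 10)
  baseline <- quantile(tic, 0.1, names = FALSE)
  peak <- max(tic)
  empty <- tibble(start_s = numeric(0), end_s = numeric(0))
  if (peak <= baseline) return(empty)
  thr <- baseline + threshold_frac * (peak - baseline)
  above <- tic >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(start_s = scan_times[starts[r$values]],
                 end_s = scan_times[ends[r$values]])
  if (nrow(runs) == 0) return(empty)
  # merge runs separated by < min_gap_s
  merged <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    if (runs$start_s[i] - merged$end_s[last] < min_gap_s) {
      merged$end_s[last] <- runs$end_s[i]
    } else {
      merged <- bind_rows(merged, runs[i, ])
    }
  }
  merged[merged$end_s - merged$start_s >= min_duration_s, ]
}

#' 0/1 exhalation indicator over scan times
#'
#' @param scan_times Scan times (s).
#' @param windows Windows from [detect_exhalations()].
#' @return Integer vector, 1 inside any window.
#' @export
exhalation_indicator <- function(scan_times, windows) {
  ind <- integer(length(scan_times))
  for (k in seq_len(nrow(windows))) {
    ind[scan_times >= windows$start_s[k] & scan_times <= windows$end_s[k]] <- 1L
  }
  ind
}

# best circular lag of x against ref by FFT cross-correlation, |lag| <= max_lag
best_lag <- function(ref, x, max_lag) {
  n <- length(ref)
  if (max_lag < 1 || all(x == 0) || all(ref == 0)) return(0L)
  cc <- Re(stats::fft(stats::fft(ref) * Conj(stats::fft(x)), inverse = TRUE)) / n
  # cc[k+1] is the correlation of x shifted forward by k (circular)
  lags <- c(0:max_lag, -(max_lag:1))
  idx <- c(1:(max_lag + 1), n - (max_lag:1) + 1)
  lags[which.max(cc[idx])]
}

circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Align scans on a common m/z grid (recursive FFT cross-correlation)
#'
#' RAFFT-style alignment: each scan (a column of `mat`, resampled onto a
#' uniform m/z grid) is shifted by the integer lag maximising its FFT
#' cross-correlation with the running reference (cumulative mean of the
#' already-aligned scans), then the correction is refined recursively on
#' halved segments. Shifts are circular, so per-scan total intensity is
#' conserved exactly. Empty scans are returned unchanged with shift 0.
#'
#' @param mat Numeric matrix, rows = m/z grid bins, columns = scans.
#' @param max_shift_bins Maximum absolute lag at the top level (halved at each
#'   recursion level).
#' @param min_segment Segments shorter than this are not split further.
#' @return List with `aligned` (matrix) and `shifts` (top-level integer lag
#'   applied to each scan).
#' @export
align_scans <- function(mat, max_shift_bins = 20, min_segment = 64) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  aligned <- mat
  shifts <- integer(ncol(mat))
  ref <- mat[, 1]
  refine <- function(ref_seg, x_seg, max_lag) {
    lag <- best_lag(ref_seg, x_seg, max_lag)
    out <- circ_shift(x_seg, lag)
    n <- length(out)
    if (n >= 2 * min_segment && max_lag >= 2) {
      half <- n %/% 2
      i1 <- 1:half; i2 <- (half + 1):n
      out[i1] <- refine(ref_seg[i1], out[i1], max_lag %/% 2)
      out[i2] <- refine(ref_seg[i2], out[i2], max_lag %/% 2)
    }
    out
  }
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    if (all(x == 0)) next
    lag <- best_lag(ref, x, max_shift_bins)
    shifts[j] <- lag
    y <- circ_shift(x, lag)
    n <- length(y)
    if (n >= 2 * min_segment && max_shift_bins >= 2) {
      half <- n %/% 2
      i1 <- 1:half; i2 <- (half + 1):n
      y[i1] <- refine(ref[i1], y[i1], max_shift_bins %/% 2)
      y[i2] <- refine(ref[i2], y[i2], max_shift_bins %/% 2)
    }
    aligned[, j] <- y
    ref <- ref + (y - ref) / (j + 1) # running mean reference
  }
  list(aligned = aligned, shifts = shifts)
}

#' Resample centroided scans onto a uniform m/z grid
#'
#' Bins centroid intensities of each scan onto a shared grid, the input
#' expected by [align_scans()].
#'
#' @param measurement A `raw_measurement`.
#' @param mz_range m/z range of the grid.
#' @param step Grid step (Th). The default quarter-FWHM at resolution 140,000
#'   and m/z 200 is appropriate for Orbitrap-class data but makes large grids;
#'   coarser steps are fine for synthetic data.
#' @return Matrix rows = grid bins (named by m/z), columns = scans.
#' @export
grid_scans <- function(measurement, mz_range = c(100, 400),
                       step = 200 / 140000 / 4) {
  grid <- seq(mz_range[1], mz_range[2], by = step)
  mat <- matrix(0, length(grid), length(measurement$scan_times))
  cc <- measurement$centroids
  if (nrow(cc) > 0) {
    bin <- pmin(pmax(round((cc$mz - mz_range[1]) / step) + 1, 1), length(grid))
    for (i in seq_len(nrow(cc))) {
      mat[bin[i], cc$scan[i]] <- mat[bin[i], cc$scan[i]] + cc$intensity[i]
    }
  }
  rownames(mat) <- formatC(grid, format = "f", digits = 4)
  mat
}

#' Consolidate pooled centroids into a feature list (KDE maxima)
#'
#' Pools per-scan centroid peaks across all measurements, estimates a kernel
#' density over pooled m/z (in log-m/z space, so the bandwidth is in ppm) and
#' takes density maxima as candidate feature centroids. A candidate is kept
#' iff at least one centroid falls within `match_tol_ppm` of it in at least
#' `min_presence` of the measurements.
#'
#' @param measurements List of `raw_measurement` objects.
#' @param kde_bandwidth_ppm Kernel bandwidth (ppm).
#' @param min_presence Minimum fraction of measurements, in (0, 1].
#' @param match_tol_ppm Matching tolerance (ppm) used for detection and stored
#'   in the feature definitions.
#' @return Tibble of feature definitions: `feature_id`, `mz`, `polarity`,
#'   `tol_ppm`, `presence_frac`, ordered by m/z.
#' @export
build_feature_list <- function(measurements, kde_bandwidth_ppm = 2,
                               min_presence = 0.1, match_tol_ppm = 5) {
  if (kde_bandwidth_ppm <= 0) stop("kde_bandwidth_ppm must be > 0", call. = FALSE)
  stopifnot(min_presence > 0, min_presence <= 1)
  empty <- tibble(feature_id = character(0), mz = numeric(0),
                  polarity = character(0), tol_ppm = numeric(0),
                  presence_frac = numeric(0))
  if (length(measurements) == 0) return(empty)
  pooled <- unlist(lapply(measurements, function(m) m$centroids$mz))
  if (length(pooled) == 0) return(empty)
  lm <- sort(log(pooled))
  bw <- kde_bandwidth_ppm * 1e-6
  # split into clusters at gaps > 4 bandwidths, then KDE maxima per cluster
  breaks <- which(diff(lm) > 4 * bw)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(lm))
  cand <- unlist(lapply(seq_along(starts), function(i) {
    seg <- lm[starts[i]:ends[i]]
    if (length(seg) < 3 || diff(range(seg)) < bw / 10) return(mean(seg))
    d <- density(seg, bw = bw, n = 256)
    y <- d$y
    top <- which(y > c(y[-1], -Inf) & y >= c(-Inf, y[-length(y)]))
    d$x[top]
  }))
  cand <- exp(sort(cand))
  polarity <- measurements[[1]]$polarity %||% "+"
  # presence across measurements
  pres <- vapply(cand, function(mzc) {
    mean(vapply(measurements, function(m) {
      any(within_ppm(m$centroids$mz, mzc, match_tol_ppm))
    }, logical(1)))
  }, numeric(1))
  keep <- pres >= min_presence
  cand <- cand[keep]; pres <- pres[keep]
  tibble(
    feature_id = sprintf("F%03d", seq_along(cand)),
    mz = cand, polarity = polarity, tol_ppm = match_tol_ppm,
    presence_frac = pres
  )
}

#' Extract the intensity time-trace of one feature
#'
#' Per scan, the sum of centroid intensities within the ppm tolerance of the
#' feature centroid; 0 where no centroid matches.
#'
#' @param measurement A `raw_measurement`.
#' @param mz Feature centroid (Th).
#' @param tol_ppm Match tolerance (ppm), > 0.
#' @return Numeric vector, one value per scan.
#' @export
extract_trace <- function(measurement, mz, tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  ns <- length(measurement$scan_times)
  cc <- measurement$centroids
  hit <- cc[within_ppm(cc$mz, mz, tol_ppm), ]
  trace <- numeric(ns)
  if (nrow(hit) > 0) {
    s <- tapply(hit$intensity, factor(hit$scan, levels = seq_len(ns)), sum)
    trace <- as.numeric(ifelse(is.na(s), 0, s))
  }
  trace
}

# scans x features trace matrix for a measurement
extract_trace_matrix <- function(measurement, features) {
  ns <- length(measurement$scan_times)
  out <- matrix(0, ns, nrow(features),
                dimnames = list(NULL, features$feature_id))
  cc <- measurement$centroids
  if (nrow(cc) == 0) return(out)
  ord <- order(features$mz)
  for (j in ord) {
    out[, j] <- extract_trace(measurement, features$mz[j], features$tol_ppm[j])
  }
  out
}

#' Breath-correlation filter over a measurement set
#'
#' Per measurement, the Spearman correlation (and its p-value) between each
#' feature trace and the exhalation indicator is computed; p-values are
#' Benjamini-Hochberg adjusted across features within the measurement. A
#' feature is kept iff `rho >= rho_min` and `q <= fdr_max` in at least a
#' `quorum` fraction of the measurements where the feature is present
#' (default: every one of them, the literal "in each measurement" rule).
#' Constant traces have undefined correlation and count as failing.
#'
#' @param traces List (one per measurement) of scans x features matrices with
#'   identical column names.
#' @param indicators List of 0/1 exhalation-indicator vectors (or any
#'   monotone breath-profile proxy), one per measurement.
#' @param presence Optional measurements x features logical matrix restricting
#'   which (measurement, feature) pairs are assessed; defaults to all.
#' @param rho_min Minimum Spearman correlation.
#' @param fdr_max Maximum BH-adjusted p.
#' @param quorum Fraction of present measurements that must satisfy the rule.
#' @return Tibble per feature: `feature_id`, `n_present`, `n_pass`, `min_rho`,
#'   `max_q`, `keep`.
#' @export
breath_correlation_filter <- function(traces, indicators, presence = NULL,
                                      rho_min = 0.6, fdr_max = 0.01,
                                      quorum = 1) {
  stopifnot(length(traces) == length(indicators), length(traces) >= 1)
  feats <- colnames(traces[[1]])
  nm <- length(traces)
  nf <- length(feats)
  if (is.null(presence)) presence <- matrix(TRUE, nm, nf)
  pass <- matrix(NA, nm, nf)
  rho_all <- matrix(NA_real_, nm, nf)
  q_all <- matrix(NA_real_, nm, nf)
  for (m in seq_len(nm)) {
    ind <- indicators[[m]]
    tested <- which(presence[m, ])
    if (length(tested) == 0) next
    rp <- vapply(tested, function(j) spearman_rho_p(traces[[m]][, j], ind),
                 numeric(2))
    q <- p.adjust(rp[2, ], method = "BH")
    rho_all[m, tested] <- rp[1, ]
    q_all[m, tested] <- q
    ok <- !is.na(rp[1, ]) & rp[1, ] >= rho_min & !is.na(q) & q <= fdr_max
    pass[m, tested] <- ok
  }
  n_present <- colSums(!is.na(pass))
  n_pass <- colSums(pass, na.rm = TRUE)
  tibble(
    feature_id = feats,
    n_present = as.integer(n_present),
    n_pass = as.integer(n_pass),
    min_rho = apply(rho_all, 2, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)),
    max_q = apply(q_all, 2, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)),
    keep = n_present > 0 & n_pass >= quorum * n_present
  )
}

#' Mean exhalation-normalised area under the curve (nAUC)
#'
#' Per window, the trapezoidal integral of the trace over
#' `[start_s, end_s]` (with linear interpolation at the window boundaries)
#' divided by the window duration; the returned value is the arithmetic mean
#' over windows.
#'
#' @param trace Intensity trace, one value per scan.
#' @param scan_times Scan times (s).
#' @param windows Tibble of windows (`start_s`, `end_s`), at least one row.
#' @return Mean nAUC (a.u.).
#' @export
compute_nauc <- function(trace, scan_times, windows) {
  stopifnot(nrow(windows) >= 1)
  if (any(windows$end_s <= windows$start_s)) {
    stop("windows must satisfy end_s > start_s", call. = FALSE)
  }
  per_window <- vapply(seq_len(nrow(windows)), function(k) {
    a <- windows$start_s[k]; b <- windows$end_s[k]
    inside <- scan_times > a & scan_times < b
    tt <- c(a, scan_times[inside], b)
    yy <- c(approx(scan_times, trace, xout = a, rule = 2)$y,
            trace[inside],
            approx(scan_times, trace, xout = b, rule = 2)$y)
    trapz(tt, yy) / (b - a)
  }, numeric(1))
  mean(per_window)
}

#' Assemble the measurements x features mean-nAUC table
#'
#' Detects exhalation windows per measurement, excludes measurements with
#' fewer than `min_exhalations` windows (recorded with a reason in the
#' `failed` slot, mirroring the study's failed-measurement accounting),
#' extracts each feature trace, computes its mean nAUC over the windows and
#' fills the presence mask (a feature is present when at least one centroid
#' falls within tolerance in at least `min_scan_frac` of in-window scans).
#' Rows and columns are deterministically ordered by id.
#'
#' @param measurements List of `raw_measurement` objects (unique ids).
#' @param features Feature definitions from [build_feature_list()] (after
#'   [breath_correlation_filter()]).
#' @param threshold_frac,min_duration_s,min_gap_s Passed to
#'   [detect_exhalations()].
#' @param min_scan_frac In-window scan fraction defining presence.
#' @param min_exhalations Minimum windows for a measurement to count.
#' @return A [feature_table].
#' @export
assemble_feature_table <- function(measurements, features,
                                   threshold_frac = 0.3, min_duration_s = 5,
                                   min_gap_s = 3, min_scan_frac = 0.25,
                                   min_exhalations = 2) {
  if (nrow(features) == 0) stop("empty feature list", call. = FALSE)
  ids <- vapply(measurements, function(m) m$measurement_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate measurement ids", call. = FALSE)
  ord <- order(ids)
  measurements <- measurements[ord]; ids <- ids[ord]
  features <- arrange(features, .data$feature_id)

  rows <- list(); pres <- list(); meta <- list(); failed <- list()
  for (m in measurements) {
    win <- detect_exhalations(m$tic, m$scan_times, threshold_frac,
                              min_duration_s, min_gap_s)
    if (nrow(win) < min_exhalations) {
      failed[[m$measurement_id]] <- tibble(
        measurement_id = m$measurement_id,
        reason = sprintf("%d exhalation window(s) detected (need >= %d)",
                         nrow(win), min_exhalations))
      next
    }
    tr <- extract_trace_matrix(m, features)
    ind <- exhalation_indicator(m$scan_times, win) == 1
    nauc <- vapply(seq_len(ncol(tr)),
                   function(j) compute_nauc(tr[, j], m$scan_times, win),
                   numeric(1))
    rows[[m$measurement_id]] <- nauc
    pres[[m$measurement_id]] <- colMeans(tr[ind, , drop = FALSE] > 0) >= min_scan_frac
    base <- tibble(
      measurement_id = m$measurement_id, subject_id = m$subject_id,
      cohort = m$cohort, batch = m$batch
    )
    meta[[m$measurement_id]] <- if (is.null(m$clinical)) base else
      dplyr::bind_cols(base, m$clinical)
  }
  if (length(rows) == 0) stop("no measurement passed exhalation detection", call. = FALSE)
  nauc <- do.call(rbind, rows)
  presence <- do.call(rbind, pres)
  new_feature_table(
    nauc = pmax(nauc, 0), presence = presence & nauc > 0,
    row_data = bind_rows(meta),
    col_data = select(features, "feature_id", "mz", "polarity", "tol_ppm"),
    failed = if (length(failed)) bind_rows(failed) else
      tibble(measurement_id = character(), reason = character())
  )
}

#' One-call feature extraction from raw measurements
#'
#' Convenience wrapper chaining [build_feature_list()],
#' [breath_correlation_filter()] and [assemble_feature_table()] with the
#' standard thresholds (10% presence, Spearman rho >= 0.6 at FDR <= 0.01 per
#' measurement).
#'
#' @inheritParams assemble_feature_table
#' @inheritParams build_feature_list
#' @inheritParams breath_correlation_filter
#' @return A [feature_table] of the breath-correlated features; the
#'   correlation-filter report is attached as attribute `"filter_report"`.
#' @export
extract_features <- function(measurements, kde_bandwidth_ppm = 2,
                             min_presence = 0.1, match_tol_ppm = 5,
                             rho_min = 0.6, fdr_max = 0.01, quorum = 1,
                             threshold_frac = 0.3, min_duration_s = 5,
                             min_gap_s = 3) {
  features <- build_feature_list(measurements, kde_bandwidth_ppm,
                                 min_presence, match_tol_ppm)
  if (nrow(features) == 0) stop("no features found", call. = FALSE)
  ok <- list(); traces <- list(); inds <- list(); pres <- list()
  for (m in measurements) {
    win <- detect_exhalations(m$tic, m$scan_times, threshold_frac,
                              min_duration_s, min_gap_s)
    if (nrow(win) < 2) next
    tr <- extract_trace_matrix(m, features)
    ind <- exhalation_indicator(m$scan_times, win)
    traces[[m$measurement_id]] <- tr
    inds[[m$measurement_id]] <- ind
    pres[[m$measurement_id]] <- colMeans(tr[ind == 1, , drop = FALSE] > 0) >= 0.25
  }
  if (length(traces) == 0) stop("no measurement passed exhalation detection", call. = FALSE)
  rep <- breath_correlation_filter(traces, inds, do.call(rbind, pres),
                                   rho_min, fdr_max, quorum)
  kept <- features[features$feature_id %in% rep$feature_id[rep$keep], ]
  if (nrow(kept) == 0) stop("no feature passed the breath-correlation filter", call. = FALSE)
  ft <- assemble_feature_table(measurements, kept, threshold_frac,
                               min_duration_s, min_gap_s)
  attr(ft, "filter_report") <- rep
  ft
}
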