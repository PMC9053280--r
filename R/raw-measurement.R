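#' Construct a raw breath measurement
#'
#' One subject visit: strictly increasing scan times, centroided spectra
#' (long tibble of `scan`, `mz`, `intensity`), per-scan total ion current and
#' the clinical annotation row.
#'
#' @param measurement_id,subject_id Unique identifiers.
#' @param cohort Cohort tag (e.g. `"paediatric"`, `"adult"`).
#' @param polarity `"+"` or `"-"`.
#' @param batch Acquisition batch label.
#' @param scan_times Numeric, strictly increasing (seconds).
#' @param centroids Tibble with columns `scan` (index into `scan_times`),
#'   `mz` (Th, within scan range 100-400) and `intensity` (>= 0).
#' @param tic Per-scan total ion current; recomputed as the per-scan intensity
#'   sum when `NULL`.
#' @param clinical One-row tibble of clinical annotation (drugs, total/free
#'   VPA in mg/L, outcome classes I-III), or `NULL`.
#' @return A `raw_measurement` object.
#' @export
new_raw_measurement <- function(measurement_id, subject_id = NA_character_,
                                cohort = "paediatric", polarity = "+",
                                batch = "B1", scan_times, centroids,
                                tic = NULL, clinical = NULL) {
  stopifnot(is.numeric(scan_times), length(scan_times) >= 1)
  if (any(diff(scan_times) <= 0)) {
    stop("scan_times must be strictly increasing", call. = FALSE)
  }
  centroids <- as_tibble(centroids)
  stopifnot(all(c("scan", "mz", "intensity") %in% names(centroids)))
  if (nrow(centroids) > 0) {
    if (any(centroids$intensity < 0)) stop("negative centroid intensity", call. = FALSE)
    if (any(centroids$scan < 1 | centroids$scan > length(scan_times))) {
      stop("centroid scan index out of range", call. = FALSE)
    }
  }
  if (is.null(tic)) {
    tic <- numeric(length(scan_times))
    if (nrow(centroids) > 0) {
      s <- tapply(centroids$intensity, factor(centroids$scan,
                                              levels = seq_along(scan_times)), sum)
      tic <- as.numeric(ifelse(is.na(s), 0, s))
    }
  }
  stopifnot(length(tic) == length(scan_times))
  structure(
    list(measurement_id = measurement_id, subject_id = subject_id,
         cohort = cohort, polarity = polarity, batch = batch,
         scan_times = as.numeric(scan_times), centroids = centroids,
         tic = as.numeric(tic),
         clinical = if (is.null(clinical)) NULL else as_tibble(clinical)),
    class = "raw_measurement"
  )
}

#' @export
print.raw_measurement <- function(x, ...) {
  cat(sprintf("<raw_measurement> %s (subject %s, batch %s, polarity %s)\n",
              x$measurement_id, x$subject_id, x$batch, x$polarity))
  cat(sprintf("  %d scans over %.1f s, %d centroids\n", length(x$scan_times),
              diff(range(x$scan_times)), nrow(x$centroids)))
  invisible(x)
}
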