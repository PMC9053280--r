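#' The measurements x features mean-nAUC table
#'
#' Central container of the pipeline: a numeric matrix of mean nAUC values
#' (rows = measurements, columns = features), a parallel logical presence
#' mask, row metadata (clinical annotation, batch, cohort) and column
#' metadata (feature m/z definitions). Missing nAUCs are stored as 0 with the
#' presence mask carrying the distinction.
#'
#' @param nauc Numeric matrix, no negative entries, unique dimnames.
#' @param presence Logical matrix of the same shape (feature detected in the
#'   measurement).
#' @param row_data Tibble keyed by `measurement_id`, aligned with rows.
#' @param col_data Tibble keyed by `feature_id`, aligned with columns; must
#'   carry `mz`.
#' @param failed Optional tibble of excluded measurements
#'   (`measurement_id`, `reason`).
#' @return A `feature_table` object.
#' @name feature_table
#' @export
new_feature_table <- function(nauc, presence = nauc > 0, row_data, col_data,
                              failed = tibble(measurement_id = character(),
                                              reason = character())) {
  stopifnot(is.matrix(nauc), is.matrix(presence),
            all(dim(nauc) == dim(presence)))
  if (any(nauc < 0)) stop("nAUC entries must be non-negative", call. = FALSE)
  row_data <- as_tibble(row_data); col_data <- as_tibble(col_data)
  stopifnot(nrow(row_data) == nrow(nauc), nrow(col_data) == ncol(nauc))
  if (anyDuplicated(row_data$measurement_id)) {
    stop("duplicate measurement ids", call. = FALSE)
  }
  if (anyDuplicated(col_data$feature_id)) stop("duplicate feature ids", call. = FALSE)
  dimnames(nauc) <- dimnames(presence) <-
    list(row_data$measurement_id, col_data$feature_id)
  structure(list(nauc = nauc, presence = presence, row_data = row_data,
                 col_data = col_data, failed = as_tibble(failed)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d measurements x %d features\n",
              nrow(x$nauc), ncol(x$nauc)))
  if (nrow(x$failed) > 0) {
    cat(sprintf("  %d failed measurement(s) excluded\n", nrow(x$failed)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$nauc)

#' Subset a feature table
#'
#' @param x A `feature_table`.
#' @param i Measurement selector (ids, indices or logical).
#' @param j Feature selector (ids, indices or logical).
#' @param ... Ignored.
#' @param drop Ignored; always returns a `feature_table`.
#' @export
`[.feature_table` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$nauc))
  if (missing(j)) j <- seq_len(ncol(x$nauc))
  if (is.character(i)) i <- match(i, rownames(x$nauc))
  if (is.character(j)) j <- match(j, colnames(x$nauc))
  new_feature_table(
    nauc = x$nauc[i, j, drop = FALSE],
    presence = x$presence[i, j, drop = FALSE],
    row_data = x$row_data[i, , drop = FALSE],
    col_data = x$col_data[j, , drop = FALSE],
    failed = x$failed
  )
}

#' Long-format view of a feature table
#'
#' @param x A `feature_table`.
#' @param ... Ignored.
#' @return Tibble with one row per (measurement, feature):
#'   `measurement_id`, `feature_id`, `nauc`, `present`.
#' @export
as_tibble.feature_table <- function(x, ...) {
  tibble(
    measurement_id = rep(rownames(x$nauc), times = ncol(x$nauc)),
    feature_id = rep(colnames(x$nauc), each = nrow(x$nauc)),
    nauc = as.vector(x$nauc),
    present = as.vector(x$presence)
  )
}

# fraction of selected measurements in which each feature is present
presence_fraction <- function(ft, rows = NULL) {
  p <- ft$presence
  if (!is.null(rows)) p <- p[rows, , drop = FALSE]
  colMeans(p)
}
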