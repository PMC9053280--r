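# Readers and writers: compact trace tables (TSV), mzXML, feature-table CSV
# bundles, pathway-database JSON. CSV dialect throughout: UTF-8, '.' decimal,
# mandatory header; times in seconds, concentrations in mg/L, m/z in Th.

#' Write / read a cohort as compact trace tables
#'
#' One TSV of centroids per cohort (`measurement_id`, `scan_index`,
#' `scan_time_s`, `mz`, `intensity`), one TSV of per-scan TICs and one CSV of
#' per-measurement annotation (ids, batch, polarity, clinical columns). The
#' round trip is lossless.
#'
#' @param measurements List of `raw_measurement` objects.
#' @param dir Output directory (created if needed).
#' @return `write_trace_table()` the directory (invisibly);
#'   `read_trace_table()` the list of measurements.
#' @export
write_trace_table <- function(measurements, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cent <- bind_rows(lapply(measurements, function(m) {
    tibble(measurement_id = m$measurement_id, scan_index = m$centroids$scan,
           scan_time_s = m$scan_times[m$centroids$scan],
           mz = m$centroids$mz, intensity = m$centroids$intensity)
  }))
  tic <- bind_rows(lapply(measurements, function(m) {
    tibble(measurement_id = m$measurement_id,
           scan_index = seq_along(m$scan_times),
           scan_time_s = m$scan_times, tic = m$tic)
  }))
  meta <- bind_rows(lapply(measurements, function(m) {
    base <- tibble(measurement_id = m$measurement_id,
                   subject_id = m$subject_id, cohort = m$cohort,
                   polarity = m$polarity, batch = m$batch)
    if (is.null(m$clinical)) base else dplyr::bind_cols(base, m$clinical)
  }))
  readr::write_tsv(cent, file.path(dir, "centroids.tsv"))
  readr::write_tsv(tic, file.path(dir, "scans.tsv"))
  readr::write_csv(meta, file.path(dir, "measurements.csv"))
  invisible(dir)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(dir) {
  cent <- readr::read_tsv(file.path(dir, "centroids.tsv"),
                          show_col_types = FALSE)
  tic <- readr::read_tsv(file.path(dir, "scans.tsv"), show_col_types = FALSE)
  meta <- readr::read_csv(file.path(dir, "measurements.csv"),
                          show_col_types = FALSE)
  clin_cols <- setdiff(names(meta), c("measurement_id", "subject_id",
                                      "cohort", "polarity", "batch"))
  lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$measurement_id[i]
    sc <- filter(tic, .data$measurement_id == id) |> arrange(.data$scan_index)
    if (any(diff(sc$scan_time_s) <= 0)) {
      stop("non-monotone scan times in measurement ", id, call. = FALSE)
    }
    cc <- filter(cent, .data$measurement_id == id)
    new_raw_measurement(
      measurement_id = id, subject_id = meta$subject_id[i],
      cohort = meta$cohort[i], polarity = meta$polarity[i],
      batch = meta$batch[i], scan_times = sc$scan_time_s,
      centroids = tibble(scan = cc$scan_index, mz = cc$mz,
                         intensity = cc$intensity),
      tic = sc$tic,
      clinical = if (length(clin_cols)) meta[i, clin_cols] else NULL
    )
  })
}

# ---- mzXML -----------------------------------------------------------------

encode_peaks <- function(mz, intensity) {
  v <- as.numeric(rbind(mz, intensity))
  gsub("[\r\n ]", "", jsonlite::base64_enc(writeBin(v, raw(), size = 4, endian = "big")))
}

decode_peaks <- function(txt, count) {
  raw <- jsonlite::base64_dec(txt)
  v <- readBin(raw, "numeric", n = 2 * count, size = 4, endian = "big")
  list(mz = v[seq(1, length(v), by = 2)],
       intensity = v[seq(2, length(v), by = 2)])
}

#' Write / read a measurement as mzXML
#'
#' Minimal centroided mzXML (32-bit network-order m/z-intensity pairs,
#' retention times in seconds). The reader tolerates a missing
#' `totIonCurrent` attribute by recomputing the TIC as the per-scan intensity
#' sum, and reports malformed scans with their scan number. Peak intensities
#' round-trip at 32-bit float precision.
#'
#' @param measurement A `raw_measurement`.
#' @param path File path.
#' @return `write_mzxml()` the path (invisibly); `read_mzxml()` a
#'   `raw_measurement` (without clinical annotation, which mzXML does not
#'   carry).
#' @export
write_mzxml <- function(measurement, path) {
  m <- measurement
  ns <- length(m$scan_times)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines('<?xml version="1.0" encoding="UTF-8"?>', con)
  writeLines('<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">', con)
  writeLines(sprintf(' <msRun scanCount="%d" measurementId="%s" subjectId="%s" batch="%s" polarity="%s">',
                     ns, m$measurement_id, m$subject_id, m$batch, m$polarity), con)
  for (s in seq_len(ns)) {
    cc <- m$centroids[m$centroids$scan == s, ]
    writeLines(sprintf('  <scan num="%d" msLevel="1" peaksCount="%d" retentionTime="PT%.4fS" totIonCurrent="%.6g">',
                       s, nrow(cc), m$scan_times[s], m$tic[s]), con)
    writeLines(sprintf('   <peaks precision="32" byteOrder="network" contentType="m/z-int">%s</peaks>',
                       if (nrow(cc)) encode_peaks(cc$mz, cc$intensity) else ""), con)
    writeLines('  </scan>', con)
  }
  writeLines(' </msRun>', con)
  writeLines('</mzXML>', con)
  invisible(path)
}

#' @rdname write_mzxml
#' @export
read_mzxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  run <- xml2::xml_find_first(doc, ".//msRun")
  if (is.na(xml2::xml_name(run))) stop("malformed mzXML: no msRun element", call. = FALSE)
  scans <- xml2::xml_find_all(run, ".//scan")
  if (length(scans) == 0) stop("malformed mzXML: no scans", call. = FALSE)
  times <- numeric(length(scans)); tic <- rep(NA_real_, length(scans))
  cents <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    num <- xml2::xml_attr(sc, "num") %||% as.character(i)
    rt <- xml2::xml_attr(sc, "retentionTime")
    if (is.na(rt) || !grepl("^PT.*S$", rt)) {
      stop("malformed mzXML: bad retentionTime in scan ", num, call. = FALSE)
    }
    times[i] <- as.numeric(sub("S$", "", sub("^PT", "", rt)))
    ti <- xml2::xml_attr(sc, "totIonCurrent")
    if (!is.na(ti)) tic[i] <- as.numeric(ti)
    count <- as.integer(xml2::xml_attr(sc, "peaksCount"))
    pk <- xml2::xml_find_first(sc, ".//peaks")
    txt <- xml2::xml_text(pk)
    if (is.na(count)) stop("malformed mzXML: missing peaksCount in scan ", num,
                           call. = FALSE)
    if (count > 0) {
      if (!nzchar(txt)) stop("malformed mzXML: empty peaks in scan ", num,
                             call. = FALSE)
      p <- decode_peaks(txt, count)
      cents[[i]] <- tibble(scan = i, mz = p$mz, intensity = p$intensity)
    }
  }
  centroids <- if (length(cents)) bind_rows(cents) else
    tibble(scan = integer(), mz = numeric(), intensity = numeric())
  attr_or <- function(node, a, default) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }
  new_raw_measurement(
    measurement_id = attr_or(run, "measurementId", basename(path)),
    subject_id = attr_or(run, "subjectId", NA_character_),
    polarity = attr_or(run, "polarity", "+"),
    batch = attr_or(run, "batch", "B1"),
    scan_times = times, centroids = centroids,
    tic = if (anyNA(tic)) NULL else tic # NULL triggers per-scan-sum fallback
  )
}

# ---- feature table bundle --------------------------------------------------

#' Write / read a feature table as a CSV bundle
#'
#' `<dir>/feature_table.csv` (rows = measurements, columns = features), a
#' clinical-metadata CSV, and a sidecar `<dir>/feature_definitions.json`
#' carrying the feature definitions, the presence mask and the
#' failed-measurement log. Round trip restores the object exactly up to
#' numeric text representation.
#'
#' @param ft A [feature_table].
#' @param dir Directory.
#' @return `write_feature_table()` the directory (invisibly);
#'   `read_feature_table()` a `feature_table`.
#' @export
write_feature_table <- function(ft, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nauc <- as_tibble(as.data.frame(ft$nauc)) |>
    mutate(measurement_id = rownames(ft$nauc), .before = 1)
  pres <- as_tibble(as.data.frame(ft$presence)) |>
    mutate(measurement_id = rownames(ft$presence), .before = 1)
  readr::write_csv(nauc, file.path(dir, "feature_table.csv"))
  readr::write_csv(ft$row_data, file.path(dir, "clinical_metadata.csv"))
  jsonlite::write_json(
    list(features = ft$col_data, presence = pres, failed = ft$failed),
    file.path(dir, "feature_definitions.json"),
    dataframe = "rows", digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(dir) {
  nauc <- readr::read_csv(file.path(dir, "feature_table.csv"),
                          show_col_types = FALSE)
  row_data <- readr::read_csv(file.path(dir, "clinical_metadata.csv"),
                              show_col_types = FALSE)
  side <- jsonlite::read_json(file.path(dir, "feature_definitions.json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(select(nauc, -"measurement_id"))
  rownames(mat) <- nauc$measurement_id
  pres <- as_tibble(side$presence)
  pm <- as.matrix(select(pres, -"measurement_id")) == TRUE
  rownames(pm) <- pres$measurement_id
  failed <- as_tibble(side$failed)
  if (nrow(failed) == 0) {
    failed <- tibble(measurement_id = character(), reason = character())
  }
  new_feature_table(nauc = mat, presence = pm, row_data = row_data,
                    col_data = as_tibble(side$features), failed = failed)
}

# ---- pathway database ------------------------------------------------------

#' Write / read a pathway database as JSON
#'
#' Documented schema: `compounds` (array of `compound_id`, `name`, `mass`,
#' `is_drug`) and `pathways` (array of `pathway_id`, `name`, `compound_ids`).
#'
#' @param db A `pathway_db`.
#' @param path File path.
#' @return `write_pathway_db()` the path (invisibly); `read_pathway_db()` a
#'   `pathway_db`.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  jsonlite::write_json(
    list(compounds = db$compounds,
         pathways = lapply(seq_len(nrow(db$pathways)), function(i) {
           list(pathway_id = db$pathways$pathway_id[i],
                name = db$pathways$name[i],
                compound_ids = db$pathways$compound_ids[[i]])
         })),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_pathway_db
#' @export
read_pathway_db <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  pw <- x$pathways
  structure(
    list(compounds = as_tibble(x$compounds),
         pathways = tibble(
           pathway_id = as.character(unlist(pw$pathway_id)),
           name = as.character(unlist(pw$name)),
           compound_ids = lapply(pw$compound_ids, function(x) unname(unlist(x)))
         )),
    class = "pathway_db"
  )
}

#' Write the synthetic ground truth as JSON
#'
#' Per-measurement programmed concentrations and classes, per-feature flags
#' and per-batch factors — everything needed to audit a synthetic run.
#'
#' @param truth A `synthetic_truth`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(
      measurements = select(truth$measurements, -"schedule"),
      features = truth$features,
      batch_factors = as.data.frame(truth$batch_factors),
      affected_pathways = truth$affected_pathways
    ),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
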