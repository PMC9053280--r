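# End-to-end pipeline: synthetic cohort (or trace-table input) -> feature
# table -> VPA concentration models -> outcome scores, with a manifest of
# every artefact written.

#' Full pipeline configuration
#'
#' Consolidates every stage parameter: the cohort generator settings, the
#' extraction thresholds (10% presence, Spearman rho >= 0.6 at FDR <= 0.01),
#' the drug-feature presence threshold (80%), the endogenous filter (50%
#' presence, CV > 30%), the importance cutoff (0.1), the dual-enrichment
#' alpha (0.05) and the therapeutic ranges. Serialises to JSON and back
#' identically.
#'
#' @param seed Master seed for the run.
#' @param cohort Named list of [cohort_config()] overrides.
#' @param input_dir Optional trace-table directory; when `NULL` a synthetic
#'   cohort is generated.
#' @param min_presence_features,rho_min,fdr_max Extraction thresholds.
#' @param min_presence_drug Drug-feature presence among VPA measurements.
#' @param min_presence_endo,min_cv Endogenous filter thresholds.
#' @param importance_cutoff Combined-weight selection cutoff.
#' @param q_gate BH gate for the significant-metabolite list.
#' @param alpha Dual-enrichment significance level.
#' @param n_perm Permutations for both enrichment algorithms.
#' @param train_fraction Fraction of subjects assigned to the training set.
#' @param align Run spectral alignment before extraction (off by default:
#'   synthetic centroids are already mass-aligned).
#' @param polarity Polarity tag processed in this run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, cohort = list(), input_dir = NULL,
                            min_presence_features = 0.1, rho_min = 0.6,
                            fdr_max = 0.01, min_presence_drug = 0.8,
                            min_presence_endo = 0.5, min_cv = 0.3,
                            importance_cutoff = 0.1, q_gate = 0.25,
                            alpha = 0.05, n_perm = 200,
                            train_fraction = 2 / 3, align = FALSE,
                            polarity = "+") {
  cfg <- list(
    seed = as.integer(seed), cohort = cohort, input_dir = input_dir,
    min_presence_features = min_presence_features, rho_min = rho_min,
    fdr_max = fdr_max, min_presence_drug = min_presence_drug,
    min_presence_endo = min_presence_endo, min_cv = min_cv,
    importance_cutoff = importance_cutoff, q_gate = q_gate, alpha = alpha,
    n_perm = n_perm, train_fraction = train_fraction, align = align,
    polarity = polarity,
    therapeutic_range = vpa_therapeutic_range
  )
  stopifnot(cfg$min_presence_features > 0, cfg$min_presence_features <= 1,
            cfg$rho_min >= -1, cfg$rho_min <= 1,
            cfg$fdr_max > 0, cfg$fdr_max <= 1,
            cfg$min_presence_drug > 0, cfg$min_presence_drug <= 1,
            cfg$min_presence_endo > 0, cfg$min_presence_endo <= 1,
            cfg$min_cv >= 0, cfg$importance_cutoff >= 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_perm >= 100,
            cfg$train_fraction > 0, cfg$train_fraction < 1)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cohort <- as.list(x$cohort)
  x$therapeutic_range <- lapply(x$therapeutic_range, as.numeric)
  do.call(pipeline_config, x[setdiff(names(x), "therapeutic_range")])
}

log_line <- function(lines, msg) {
  message(msg)
  c(lines, msg)
}

#' Run the complete analysis pipeline
#'
#' Simulates (or reads) a cohort, extracts the feature table, trains the
#' total- and free-VPA eGPR models on a subject-level training split and
#' evaluates concordance on the held-out measurements, runs the outcome
#' branch for side effects and drug response, and writes every artefact with
#' a manifest (parameter set, package version, per-file MD5). Deterministic
#' given config + seed; a stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for the run.
#' @return Invisibly, a list with the main in-memory objects (`feature_table`,
#'   `vpa`, `outcomes`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- cohort ---------------------------------------------------------------
  db <- NULL; truth <- NULL
  measurements <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      run_log <- log_line(run_log, paste("reading trace tables from", config$input_dir))
      read_trace_table(config$input_dir)
    } else {
      cc <- do.call(cohort_config,
                    modifyList(list(seed = config$seed), config$cohort))
      sim <- simulate_cohort(cc)
      truth <- sim$truth
      db <- sim$truth$pathway_db
      run_log <- log_line(run_log, sprintf("simulated %d measurements (seed %d)",
                                    length(sim$measurements), config$seed))
      sim$measurements
    }
  })
  if (is.null(db)) db <- make_toy_pathway_db(seed = config$seed + 7013L)

  # --- extraction -----------------------------------------------------------
  ft <- stage("extract", {
    if (config$align) {
      measurements <- lapply(measurements, function(m) {
        g <- grid_scans(m, step = 0.01)
        al <- align_scans(g)$aligned
        keep <- which(al > 0, arr.ind = TRUE)
        m$centroids <- tibble(scan = keep[, 2],
                              mz = as.numeric(rownames(al))[keep[, 1]],
                              intensity = al[keep]) |>
          arrange(.data$scan, .data$mz)
        m
      })
    }
    extract_features(measurements,
                     min_presence = config$min_presence_features,
                     rho_min = config$rho_min, fdr_max = config$fdr_max)
  })
  run_log <- log_line(run_log, sprintf("feature table: %d x %d (%d failed measurements)",
                               nrow(ft$nauc), ncol(ft$nauc), nrow(ft$failed)))
  write_feature_table(ft, out_dir)

  # --- VPA branch -----------------------------------------------------------
  vpa <- stage("train-vpa", {
    if (!any(ft$row_data$total_vpa_mgL > 0)) stop("no VPA measurements")
    train_vpa_models(ft, config)
  })
  run_log <- log_line(run_log, sprintf(
    "VPA models: %d/%d predictors selected; test CCC total %.2f, free %.2f",
    sum(vpa$importance$selected), nrow(vpa$importance),
    vpa$ccc$ccc[vpa$ccc$target == "total" & vpa$ccc$subset == "vpa_only"],
    vpa$ccc$ccc[vpa$ccc$target == "free" & vpa$ccc$subset == "vpa_only"]))
  readr::write_csv(vpa$predictions, file.path(out_dir, "vpa_predictions.csv"))
  readr::write_csv(
    dplyr::bind_rows(
      mutate(as_tibble(vpa$importance), section = "importance"),
      mutate(vpa$ccc, section = "concordance")),
    file.path(out_dir, "vpa_model_report.csv"))

  # --- outcome branch -------------------------------------------------------
  outcomes <- stage("outcome-score", {
    lapply(c(side_effects = "side_effects", response = "response"),
           function(oc) {
             outcome_workflow(ft, oc, db,
                              min_presence = config$min_presence_endo,
                              min_cv = config$min_cv, q_gate = config$q_gate,
                              alpha = config$alpha, n_perm = config$n_perm,
                              seed = config$seed)
           })
  })
  enr <- bind_rows(lapply(outcomes, function(o) {
    mutate(as_tibble(o$enrichment), outcome = o$outcome)
  }))
  readr::write_csv(enr, file.path(out_dir, "enrichment.csv"))
  scores <- bind_rows(lapply(outcomes, function(o) {
    if (is.null(o$model)) return(tibble())
    pr <- predict(o$model, ft$nauc)
    tibble(outcome = o$outcome, measurement_id = rownames(ft$nauc),
           score = pr$score, predicted_positive = pr$predicted_positive,
           actual_positive = o$positive)
  }))
  readr::write_csv(scores, file.path(out_dir, "outcome_scores.csv"))
  for (o in outcomes) {
    run_log <- log_line(run_log, sprintf(
      "outcome %s: %d selected pathway(s), %d member feature(s)%s",
      o$outcome, sum(o$enrichment$selected), length(o$members),
      if (is.null(o$model)) " (no score model)" else
        sprintf(", J = %.2f", o$model$youden_j)))
  }

  # --- manifest -------------------------------------------------------------
  artefacts <- c("feature_table.csv", "clinical_metadata.csv",
                 "feature_definitions.json", "vpa_predictions.csv",
                 "vpa_model_report.csv", "enrichment.csv", "outcome_scores.csv")
  artefacts <- artefacts[file.exists(file.path(out_dir, artefacts))]
  manifest <- list(
    package = "breathtdm",
    version = as.character(utils::packageVersion("breathtdm")),
    seed = config$seed,
    parameters = unclass(config),
    failed_measurements = ft$failed,
    artefacts = tibble(
      file = artefacts,
      md5 = unname(tools::md5sum(file.path(out_dir, artefacts)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  writeLines(run_log, file.path(out_dir, "log.txt"))
  invisible(list(feature_table = ft, vpa = vpa, outcomes = outcomes,
                 truth = truth, manifest = manifest))
}

#' Train total- and free-VPA regression models on a feature table
#'
#' The concentration branch: 80%-presence drug-feature filter among VPA
#' measurements, RReliefF + bagged-forest importance combined with the
#' empirical cutoff, batch adjustment, then one exponential-kernel GP per
#' target (total and free serum VPA) trained on a subject-level split with
#' non-VPA measurements included at target 0. Concordance is reported with
#' and without the zero (non-VPA) test points.
#'
#' @param ft A [feature_table] whose row metadata carries `total_vpa_mgL`,
#'   `free_vpa_mgL`, `batch` and `subject_id`.
#' @param config A [pipeline_config()].
#' @return List: `importance`, `models` (per target), `predictions`, `ccc`.
#' @export
train_vpa_models <- function(ft, config = pipeline_config()) {
  drug <- filter_drug_features(ft, config$min_presence_drug)
  y_total <- ft$row_data$total_vpa_mgL
  X <- drug$nauc
  relief <- rrelieff_weights(X, y_total, k_neighbors = min(10, nrow(X) - 1))
  forest <- forest_importance(X, y_total, seed = config$seed)
  imp <- combine_and_select(relief, forest, cutoff = config$importance_cutoff)
  sel <- imp$feature_id[imp$selected]
  if (length(sel) < 1) stop("no predictor passed the importance cutoff", call. = FALSE)
  Xs <- X[, sel, drop = FALSE]
  batch <- ft$row_data$batch
  if (length(unique(batch)) > 1 && min(table(batch)) >= 2) {
    Xs <- combat_adjust(Xs, batch)
  }
  subjects <- unique(ft$row_data$subject_id)
  # split seed decoupled from the cohort seed so the subject-level split is
  # independent of any subject-level draw made by the generator
  train_subj <- with_seed(config$seed * 7919L + 257L, {
    sample(subjects, ceiling(config$train_fraction * length(subjects)))
  })
  tr <- ft$row_data$subject_id %in% train_subj
  targets <- list(total = y_total, free = ft$row_data$free_vpa_mgL)
  models <- list(); preds <- list(); cccs <- list()
  for (tg in names(targets)) {
    y <- targets[[tg]]
    ok <- !is.na(y)
    fit <- fit_egpr(Xs[tr & ok, , drop = FALSE], y[tr & ok],
                    seed = config$seed)
    te <- !tr & ok
    pred <- predict(fit, Xs[te, , drop = FALSE])
    models[[tg]] <- fit
    preds[[tg]] <- tibble(
      target = tg, measurement_id = rownames(Xs)[te],
      actual_mgL = y[te], predicted_mgL = pred,
      on_vpa = ft$row_data$total_vpa_mgL[te] > 0
    )
    on <- preds[[tg]]$on_vpa
    cccs[[tg]] <- bind_rows(
      mutate(lin_ccc(y[te], pred), target = tg, subset = "all"),
      if (sum(on) >= 2) {
        mutate(lin_ccc(y[te][on], pred[on]), target = tg, subset = "vpa_only")
      }
    )
  }
  list(importance = imp, models = models,
       predictions = bind_rows(preds), ccc = bind_rows(cccs),
       selected = sel, train_subjects = train_subj)
}
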