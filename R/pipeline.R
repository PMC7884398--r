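#' End-to-end run configuration
#'
#' Bundles everything one pipeline run needs: the manifest, the output
#' directory, SOM and LVQ configurations, and cross-validation options.
#' All seeds live inside the SOM/LVQ/CV configurations and are recorded
#' in the run's provenance log, so a rerun with an identical
#' configuration reproduces every artifact bit-exactly.
#'
#' @param manifest Path to the cohort manifest.
#' @param out_dir Run output directory.
#' @param som A `som_config`.
#' @param lvq An `lvq_config`.
#' @param cv_k Holdout size for leave-k-out cross-validation over the
#'   combined training + validation cohort.
#' @param cv_threshold Accuracy threshold (percent) for model selection.
#' @param cv_balanced_only Restrict model selection to class-balanced
#'   splits.
#' @param cv_max_splits Cap on evaluated splits (seeded subsample);
#'   `NULL` runs the exhaustive enumeration.
#' @param cv_seed Seed for the split subsample.
#' @param run_cv Whether to run the cross-validation stage at all.
#' @return A `run_config` object.
#' @export
run_config <- function(manifest, out_dir, som = som_config(),
                       lvq = lvq_config(), cv_k = 6L, cv_threshold = 83,
                       cv_balanced_only = FALSE, cv_max_splits = 100L,
                       cv_seed = 7L, run_cv = TRUE) {
  stopifnot(inherits(som, "som_config"), inherits(lvq, "lvq_config"))
  structure(list(manifest = manifest, out_dir = out_dir, som = som,
                 lvq = lvq, cv_k = as.integer(cv_k),
                 cv_threshold = cv_threshold,
                 cv_balanced_only = isTRUE(cv_balanced_only),
                 cv_max_splits = cv_max_splits,
                 cv_seed = as.integer(cv_seed), run_cv = isTRUE(run_cv)),
            class = "run_config")
}

#' Run the full SOM-LVQ pipeline
#'
#' Executes the whole workflow on a manifest of co-registered studies:
#'
#' 1. load every study; calibrate tumor voxels against the subject's
#'    contralateral cortex;
#' 2. fit channel statistics on pooled training + validation voxels
#'    (the leakage guard rejects any test-cohort table) and
#'    variance-normalize all cohorts with those frozen statistics;
#' 3. train the SOM on pooled training-cohort voxels;
#' 4. compute an activation map for every subject;
#' 5. train the LVQ on training-cohort maps and evaluate it on the
#'    validation cohort ("simple validation"); optionally run leave-k-out
#'    cross-validation over training + validation and apply threshold /
#'    balance model selection;
#' 6. finalize the simple-validation model and evaluate the held-out
#'    test cohort;
#' 7. write all artifacts (channel stats, SOM, maps, LVQ model, CV
#'    table, predictions, a cohort metrics table, and a provenance log).
#'
#' Test-cohort subjects never influence the channel statistics, the SOM,
#' or LVQ training/selection; the provenance log records exactly which
#' subjects entered each stage.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `metrics` (per-cohort metric rows),
#'   `predictions`, `som`, `lvq`, `cv` (or `NULL`), `selected`,
#'   `channel_stats`, `maps`, and `out_dir`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "maps"), showWarnings = FALSE)

  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s%s] %s", name,
                   if (is.null(sid)) "" else paste0(" / ", sid),
                   conditionMessage(e)), call. = FALSE))
  }

  manifest <- stage("read_manifest", NULL, read_manifest(config$manifest))

  tables <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    sid <- rec$subject_id
    tables[[sid]] <- stage("calibrate", sid, {
      study <- load_study(rec, base_dir = attr(manifest, "manifest_dir"))
      calibrate(study, compute_cortex_reference(study))
    })
  }

  cohort <- stats::setNames(manifest$cohort, manifest$subject_id)
  labels <- stats::setNames(manifest$class, manifest$subject_id)
  trainval_ids <- names(cohort)[cohort %in% c("training", "validation")]
  train_ids <- names(cohort)[cohort == "training"]
  test_ids <- names(cohort)[cohort == "test"]

  stats_fit <- stage("fit_channel_stats", NULL,
                     fit_channel_stats(tables[trainval_ids]))
  save_channel_stats(stats_fit, file.path(out, "channel_stats.json"))
  norm <- lapply(tables, normalize_table, stats = stats_fit)

  train_pool <- do.call(rbind, norm[train_ids])
  attr(train_pool, "stage") <- "normalized"
  som <- stage("train_som", NULL, {
    train_som(init_som(config$som, train_pool), train_pool)
  })
  save_som_model(som, file.path(out, "som_model.json"))

  maps <- list()
  for (sid in names(norm)) {
    maps[[sid]] <- stage("activation_map", sid,
                         compute_activation_map(som, norm[[sid]], sid))
    write_activation_map(maps[[sid]], file.path(out, "maps",
                                                paste0(sid, ".csv")))
  }
  vectors <- do.call(rbind, lapply(maps, flatten_map))
  rownames(vectors) <- names(maps)

  lvq <- stage("train_lvq", NULL,
               train_lvq(vectors[train_ids, , drop = FALSE],
                         labels[train_ids], config$lvq))
  save_lvq_model(lvq, file.path(out, "lvq_model.json"))

  cv_table <- NULL
  selected <- NULL
  if (config$run_cv) {
    splits <- stage("cross_validate", NULL,
      enumerate_leave_k_out(trainval_ids, config$cv_k,
                            labels[trainval_ids],
                            max_splits = config$cv_max_splits,
                            seed = config$cv_seed))
    cv_table <- stage("cross_validate", NULL,
                      cross_validate(vectors[trainval_ids, , drop = FALSE],
                                     labels[trainval_ids], config$lvq,
                                     splits))
    write.csv(cv_table, file.path(out, "cv_results.csv"), row.names = FALSE)
    selected <- select_model(cv_table, config$cv_threshold,
                             config$cv_balanced_only)
  }

  predictions <- data.frame(
    subject_id = names(maps),
    cohort = cohort[names(maps)],
    truth = labels[names(maps)],
    predicted = predict(lvq, vectors),
    row.names = NULL)
  write.csv(predictions, file.path(out, "predictions.csv"),
            row.names = FALSE)

  metrics <- lapply(cohort_levels(), function(co) {
    sub <- predictions[predictions$cohort == co &
                         predictions$truth != "unknown", ]
    if (nrow(sub) == 0) return(NULL)
    confusion_metrics(confusion_counts(sub$truth, sub$predicted))
  })
  names(metrics) <- cohort_levels()
  metrics <- Filter(Negate(is.null), metrics)

  metrics_df <- do.call(rbind, lapply(names(metrics), function(co) {
    m <- metrics[[co]]
    data.frame(cohort = co,
               accuracy_pct = round(m$accuracy, 2),
               fpr_pct = round(m$fpr, 2),
               fnr_pct = round(m$fnr, 2),
               ppv_pct = round(m$ppv, 2),
               npv_pct = round(m$npv, 2))
  }))
  write.csv(metrics_df, file.path(out, "metrics.csv"), row.names = FALSE)

  provenance <- list(
    package_version = as.character(packageVersion("somlvq")),
    manifest = normalizePath(config$manifest),
    seeds = list(som = config$som$seed, lvq = config$lvq$seed,
                 cv = config$cv_seed),
    som_config = unclass(config$som),
    lvq_config = unclass(config$lvq),
    cv = list(k = config$cv_k, threshold = config$cv_threshold,
              balanced_only = config$cv_balanced_only,
              max_splits = config$cv_max_splits, run = config$run_cv),
    stats_pool_subjects = trainval_ids,
    som_training_subjects = train_ids,
    lvq_training_subjects = train_ids,
    cv_subjects = if (config$run_cv) trainval_ids else character(0),
    test_subjects = test_ids
  )
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, metrics_table = metrics_df,
                 predictions = predictions, som = som, lvq = lvq,
                 cv = cv_table, selected = selected,
                 channel_stats = stats_fit, maps = maps, out_dir = out))
}
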