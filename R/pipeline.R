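# Top-level orchestration: scale -> folds -> select -> (tune) -> evaluate,
# with all artifacts written to a directory.

default_config <- function() {
  list(matrix = NULL, dialect = "tsv", orientation = "samples-as-rows",
       label_column = "label", positive_label = NULL,
       simulate = NULL,                  # list of simulation_spec() args
       k = 8, seed = 7,
       threshold = "sweep", sweep_grid = "0:0.9:0.1",
       min_votes = "auto", n_final = 50, r_max = 0.5,
       prune_scope = "within-class", second_pass_prune = FALSE,
       use_embedded_svm = FALSE, use_mrmr_union = FALSE,
       provider = list(nrounds = 150, max_depth = 3, learning_rate = 0.1,
                       colsample = 0.5),
       tune_trials = 0, tune_backend = "adaptive-sequential",
       classifiers = "catboost-style",
       scale_mode = "per-fold", figures = TRUE,
       out_dir = "genevote_out")
}

parse_grid <- function(g) {
  if (is.numeric(g)) return(g)
  parts <- as.numeric(strsplit(g, ":")[[1]])
  if (length(parts) != 3 || anyNA(parts))
    stopf("grid must be numeric or 'from:to:by' (got '%s')", g)
  seq(parts[1], parts[2], by = parts[3])
}

#' Run the full pipeline from a configuration
#'
#' Executes the complete flow: load (or simulate) the expression matrix,
#' min-max scale it, build stratified folds, run the hybrid gene selection
#' (importance voting, optional embedded-SVM / mRMR union, correlation
#' pruning), optionally tune classifier hyperparameters on the selected
#' genes, evaluate every requested classifier by stratified k-fold CV, and
#' write all artifacts to `out_dir`: `selected.tsv`, `metrics.json`,
#' `report.tsv`, `stage_counts.json`, `folds.tsv`, correlation TSV and
#' figures, plus `config_used.yml`.
#'
#' @param config a named list, or path to a flat YAML file, with keys
#'   mirroring the CLI flags; unspecified keys take documented defaults.
#'   Either `matrix` (a file path) or `simulate` (a list of
#'   [simulation_spec()] arguments) must be given.
#' @return invisible list with `selection`, `metrics` (per classifier),
#'   `report`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$matrix) && is.null(cfg$simulate))
    stopf("config must provide either 'matrix' (a path) or 'simulate'")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  stage <- function(name, expr) {
    logf("stage %s: start (seed %d)", name, cfg$seed)
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s (partial artifacts in %s)",
            name, conditionMessage(e), cfg$out_dir)
    })
  }

  truth <- NULL
  m <- stage("load", {
    if (!is.null(cfg$matrix)) {
      read_matrix(cfg$matrix, dialect = cfg$dialect,
                  orientation = cfg$orientation,
                  label_column = cfg$label_column,
                  positive_label = cfg$positive_label)
    } else {
      sim <- do.call(simulation_spec, cfg$simulate)
      ds <- generate_dataset(sim)
      truth <- ds$truth
      ds$matrix
    }
  })
  logf("loaded %d samples x %d genes", nrow(m$values), ncol(m$values))

  scaled <- stage("scale", scale_minmax(m))
  folds <- stage("folds", make_folds(m$labels, cfg$k, seed = cfg$seed))
  write_folds(folds, m$sample_ids, file.path(cfg$out_dir, "folds.tsv"))

  sel_cfg <- selector_config(
    threshold = if (identical(cfg$threshold, "sweep")) "sweep"
                else as.numeric(cfg$threshold),
    sweep_grid = parse_grid(cfg$sweep_grid), min_votes = cfg$min_votes,
    n_final = cfg$n_final, r_max = cfg$r_max,
    prune_scope = cfg$prune_scope,
    second_pass_prune = cfg$second_pass_prune,
    use_embedded_svm = cfg$use_embedded_svm,
    use_mrmr_union = cfg$use_mrmr_union, seed = cfg$seed)
  provider <- do.call(gbt_provider, c(cfg$provider, list(seed = cfg$seed)))
  selection <- stage("select", select_genes(scaled, folds, sel_cfg, provider))
  logf("selected %d genes at threshold %g", length(selection$genes),
       selection$threshold)
  utils::write.table(as.data.frame(selection$genes),
                     file.path(cfg$out_dir, "selected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(selection$stage_counts,
                       file.path(cfg$out_dir, "stage_counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  tuned_params <- list()
  if (cfg$tune_trials > 0) {
    tuned <- stage("tune", {
      sub <- subset_matrix(m, genes = selection$genes$gene_ids)
      obj <- make_cv_objective(sub, k = cfg$k,
                               classifier = cfg$classifiers[1],
                               seed = cfg$seed)
      tune(obj, builtin_space(cfg$classifiers[1]),
           n_trials = cfg$tune_trials, seed = cfg$seed,
           backend = cfg$tune_backend)
    })
    tuned_params[[cfg$classifiers[1]]] <- tuned$best$config
    utils::write.table(tuned$history,
                       file.path(cfg$out_dir, "trials.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("tuned %s: best loss %.4f at trial %d", cfg$classifiers[1],
         tuned$best$loss, tuned$best$index)
  }

  metrics <- list()
  report <- NULL
  for (clf in cfg$classifiers) {
    ms <- stage(paste0("evaluate-", clf), {
      cross_validate(m, genes = selection$genes, folds = folds,
                     classifier = clf,
                     params = tuned_params[[clf]] %||% list(),
                     seed = cfg$seed, scale_mode = cfg$scale_mode)
    })
    metrics[[clf]] <- list(
      per_fold = ms$per_fold,
      summary = cbind(metric = rownames(ms$summary), ms$summary),
      formatted = stats::setNames(
        lapply(rownames(ms$summary), function(mm)
          fmt_mean_sd(ms$summary[mm, "mean"], ms$summary[mm, "sd"])),
        rownames(ms$summary)),
      auc_mean_of_folds = ms$summary["auc", "mean"],
      auc_from_mean_rates = ms$auc_from_mean_rates)
    if (is.null(report)) {
      cr <- class_report(ms$oof$y_true, ms$oof$y_pred)
      report <- cr
      rep_df <- cr$per_class
      rep_df[, 2:4] <- round_half_away(as.matrix(rep_df[, 2:4]), 2)
      utils::write.table(rep_df, file.path(cfg$out_dir, "report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")

  if (isTRUE(cfg$figures) && length(selection$genes) >= 2) {
    stage("figures", correlation_report(
      scaled, selection$genes, file.path(cfg$out_dir, "selected")))
  }
  if (!is.null(selection$sweep_curve)) {
    utils::write.table(selection$sweep_curve,
                       file.path(cfg$out_dir, "threshold_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    write_truth(truth, file.path(cfg$out_dir, "truth.tsv"))
  }
  yaml::write_yaml(cfg[order(names(cfg))],
                   file.path(cfg$out_dir, "config_used.yml"))
  logf("pipeline complete")
  invisible(list(selection = selection, metrics = metrics, report = report,
                 truth = truth, out_dir = cfg$out_dir))
}
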