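# Classifier contract, stratified k-fold evaluation and correlation reports.

# Map a catboost-style parameter vocabulary onto the boosted-tree backend.
# random_strength and bagging_temperature have no analogue here and are
# accepted but inert.
catboost_style_params <- function(p) {
  list(nrounds = as.integer(p$iterations %||% 150),
       max_depth = as.integer(p$depth %||% 3),
       eta = p$learning_rate %||% 0.1,
       colsample_bylevel = p$rsm %||% 1,
       subsample = p$subsample %||% 1,
       lambda = p$l2_leaf_reg %||% 1,
       scale_pos_weight = p$scale_pos_weight %||% 1)
}

xgboost_style_params <- function(p) {
  list(nrounds = as.integer(p$n_estimators %||% 150),
       max_depth = as.integer(p$max_depth %||% 3),
       eta = p$learning_rate %||% 0.1,
       min_child_weight = p$min_child_weight %||% 1,
       gamma = p$gamma %||% 0,
       subsample = p$subsample %||% 1,
       colsample_bytree = p$colsample_bytree %||% 1)
}

fit_predict_gbt <- function(mapped, seed) {
  nrounds <- mapped$nrounds
  mapped$nrounds <- NULL
  params <- c(list(objective = "binary:logistic", nthread = 1,
                   seed = as.integer(seed)), mapped)
  function(xtr, ytr, xte) {
    dm <- xgboost::xgb.DMatrix(xtr, label = ytr, nthread = 1)
    bst <- xgboost::xgb.train(params, dm, nrounds = nrounds, verbose = 0)
    p <- stats::predict(bst, xgboost::xgb.DMatrix(xte, nthread = 1))
    list(pred = as.integer(p > 0.5), score = p)
  }
}

#' Build a seeded classifier function
#'
#' Uniform contract over the comparison classifiers: returns a
#' `function(train_values, train_labels, test_values)` yielding hard 0/1
#' predictions (and a score when the backend provides one).
#'
#' @param classifier one of `"catboost-style"`, `"xgboost-style"` (two
#'   hyperparameter vocabularies over the boosted-tree backend), `"svm"`
#'   (linear kernel), `"random-forest"`, `"naive-bayes"`.
#' @param params named list in the classifier's vocabulary (boosted-tree
#'   styles only; see [builtin_space()]).
#' @param seed integer seed fixed across folds.
#' @return classifier function.
#' @export
make_classifier <- function(classifier = c("catboost-style", "xgboost-style",
                                           "svm", "random-forest",
                                           "naive-bayes"),
                            params = list(), seed = 0) {
  classifier <- match.arg(classifier)
  switch(classifier,
    "catboost-style" = fit_predict_gbt(catboost_style_params(params), seed),
    "xgboost-style" = fit_predict_gbt(xgboost_style_params(params), seed),
    "svm" = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "linear",
                        scale = FALSE)
      list(pred = as.integer(as.character(stats::predict(fit, xte))),
           score = NULL)
    },
    "random-forest" = function(xtr, ytr, xte) {
      fit <- with_seed(seed, randomForest::randomForest(
        xtr, factor(ytr, levels = 0:1)))
      list(pred = as.integer(as.character(stats::predict(fit, xte))),
           score = stats::predict(fit, xte, type = "prob")[, "1"])
    },
    "naive-bayes" = function(xtr, ytr, xte) {
      # guard zero-variance genes, which break the Gaussian likelihood
      keep <- apply(xtr, 2, stats::sd) > 0
      if (!any(keep)) keep[1] <- TRUE
      fit <- e1071::naiveBayes(xtr[, keep, drop = FALSE],
                               factor(ytr, levels = 0:1))
      list(pred = as.integer(as.character(
        stats::predict(fit, xte[, keep, drop = FALSE]))),
        score = NULL)
    })
}

#' Stratified k-fold evaluation
#'
#' Trains on all samples outside each fold and tests on the fold, reporting
#' accuracy, sensitivity, specificity and AUC (closed form from the fold's
#' hard-prediction rates) as mean ± SD over folds. Min-max scaling is
#' fitted on each training side and applied to the fold. When a `selector`
#' function is supplied, gene selection is also re-run inside each
#' training fold (nested, leakage-free evaluation); a fixed `genes` set is
#' evaluated as-is.
#'
#' @param matrix ExpressionMatrix (unscaled; scaling is per-fold).
#' @param genes optional [gene_set()] restricting the features.
#' @param folds FoldSpec.
#' @param classifier,params,seed see [make_classifier()].
#' @param selector optional `function(train_matrix)` returning a
#'   [gene_set()], applied per training fold.
#' @param scale_mode `"per-fold"` (default: ranges fitted on each training
#'   side only), `"global"` (one transform fitted on all samples up front,
#'   as when data arrive pre-scaled) or `"none"`.
#' @param score_auc also compute a rank-based AUC from classifier scores
#'   when available (needs the pROC package).
#' @return object of class `metric_summary`: list with `per_fold`
#'   (data.frame), `summary` (metric x mean/sd), `oof` (out-of-fold
#'   predictions per sample), `auc_from_mean_rates` (the closed form
#'   applied to mean sensitivity/specificity), `k`.
#' @export
cross_validate <- function(matrix, genes = NULL, folds,
                           classifier = "catboost-style", params = list(),
                           seed = 0, selector = NULL, score_auc = FALSE,
                           scale_mode = c("per-fold", "global", "none")) {
  scale_mode <- match.arg(scale_mode)
  clf <- make_classifier(classifier, params, seed)
  if (!is.null(genes)) matrix <- subset_matrix(matrix, genes = genes$gene_ids)
  if (scale_mode == "global") matrix <- scale_minmax(matrix)
  folded <- lapply(seq_len(folds$k), function(f) {
    te <- folds$assignment == f
    train <- subset_matrix(matrix, samples = which(!te))
    test <- subset_matrix(matrix, samples = which(te))
    pred <- NULL
    score <- NULL
    if (!is.null(selector)) {
      sel <- selector(train)
      if (length(sel) > 0) {
        train <- subset_matrix(train, genes = sel$gene_ids)
        test <- subset_matrix(test, genes = sel$gene_ids)
      } else {
        # empty selection: fall back to the training majority class
        pred <- rep(as.integer(mean(train$labels) > 0.5),
                    length(test$labels))
      }
    }
    if (is.null(pred)) {
      if (scale_mode == "per-fold") {
        test <- scale_minmax(train, test)
        train <- scale_minmax(train)
      }
      out <- clf(train$values, train$labels, test$values)
      pred <- out$pred
      score <- out$score
    }
    cc <- confusion(test$labels, pred)
    sen <- suppressWarnings(sensitivity(cc))
    spe <- suppressWarnings(specificity(cc))
    sauc <- NA_real_
    if (score_auc && !is.null(score) &&
        length(unique(test$labels)) == 2 &&
        requireNamespace("pROC", quietly = TRUE)) {
      sauc <- as.numeric(pROC::auc(pROC::roc(test$labels, score,
                                             quiet = TRUE,
                                             direction = "<", levels = c(0, 1))))
    }
    list(row = data.frame(fold = f,
                          accuracy = (cc$tp + cc$tn) / length(test$labels),
                          sensitivity = sen, specificity = spe,
                          auc = auc_from_rates(sen, 1 - spe),
                          score_auc = sauc),
         oof = data.frame(sample_id = test$sample_ids, fold = f,
                          y_true = test$labels, y_pred = pred,
                          stringsAsFactors = FALSE))
  })
  per_fold <- do.call(rbind, lapply(folded, `[[`, "row"))
  oof <- do.call(rbind, lapply(folded, `[[`, "oof"))
  metrics <- c("accuracy", "sensitivity", "specificity", "auc")
  summary <- data.frame(
    mean = vapply(per_fold[metrics], mean, numeric(1)),
    sd = vapply(per_fold[metrics], stats::sd, numeric(1)),
    row.names = metrics)
  structure(list(per_fold = per_fold, summary = summary, oof = oof,
                 auc_from_mean_rates = auc_from_rates(
                   summary["sensitivity", "mean"],
                   1 - summary["specificity", "mean"]),
                 k = folds$k, classifier = classifier),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", x$k, x$classifier))
  for (m in rownames(x$summary)) {
    cat(sprintf("  %-12s %s\n", m,
                fmt_mean_sd(x$summary[m, "mean"], x$summary[m, "sd"])))
  }
  invisible(x)
}

#' Correlation matrix, heat map and dendrogram for a gene set
#'
#' Writes the symmetric Pearson correlation matrix of the selected genes
#' as TSV, a correlation heat map as PNG, and an average-linkage
#' hierarchical-clustering dendrogram on correlation distance (1 - r).
#'
#' @param matrix ExpressionMatrix.
#' @param genes [gene_set()] of genes to report on (>= 2 genes).
#' @param out_prefix path prefix for `<prefix>_correlation.tsv`,
#'   `<prefix>_heatmap.png`, `<prefix>_dendrogram.png`.
#' @return invisible list with `cor` (the matrix) and the file paths.
#' @export
correlation_report <- function(matrix, genes, out_prefix) {
  ids <- genes$gene_ids
  if (length(ids) < 2) stopf("correlation report needs at least two genes")
  v <- matrix$values[, ids, drop = FALSE]
  cm <- suppressWarnings(stats::cor(v))
  cm[is.na(cm)] <- 0 # constant genes: no correlation
  diag(cm) <- 1
  paths <- list(correlation = paste0(out_prefix, "_correlation.tsv"),
                heatmap = paste0(out_prefix, "_heatmap.png"),
                dendrogram = paste0(out_prefix, "_dendrogram.png"))
  utils::write.table(round(cm, 6), paths$correlation, sep = "\t",
                     quote = FALSE, col.names = NA)
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  grDevices::png(paths$heatmap, width = 900, height = 800)
  pheatmap::pheatmap(cm, cluster_rows = hc, cluster_cols = hc,
                     main = "Correlation among selected genes")
  grDevices::dev.off()
  grDevices::png(paths$dendrogram, width = 900, height = 500)
  plot(hc, main = "Hierarchical clustering of selected genes (1 - r)",
       xlab = "", sub = "")
  grDevices::dev.off()
  invisible(c(list(cor = cm), paths))
}
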