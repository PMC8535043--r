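# Core selection algorithm: per-fold importances, threshold filtering with
# optional accuracy-driven sweep, cross-fold voting, embedded-SVM ranking,
# unique-merge and correlation pruning.

#' Selector configuration
#'
#' @param threshold importance cutoff in \[0, 1\] applied to max-normalised
#'   per-fold importances, or `"sweep"` to pick the accuracy-maximising
#'   grid point (see [sweep_threshold()]).
#' @param sweep_grid ascending grid of candidate thresholds used when
#'   `threshold = "sweep"`.
#' @param min_votes minimum number of folds a gene must survive in, or
#'   `"auto"` for `ceiling(0.75 * k)` (three-quarters consensus, in line
#'   with stability-selection practice).
#' @param n_final target number of genes after voting (default 50).
#' @param r_max correlation-pruning cutoff: of two kept genes no pair may
#'   reach `|r| >= r_max` (default 0.5).
#' @param prune_scope correlation scope for pruning, `"within-class"`
#'   (default) or `"marginal"`; see [correlation_prune()].
#' @param second_pass_prune run a second pruning pass at `r_max + 0.01`
#'   (off by default).
#' @param use_embedded_svm also rank genes by per-fold linear-SVM weights
#'   and union them in before pruning.
#' @param use_mrmr_union union the heads of an exhaustive mRMR ensemble
#'   into the candidate set before pruning.
#' @param seed integer seed driving the unique-merge shuffle and any
#'   provider randomness.
#' @return object of class `selector_config`.
#' @export
selector_config <- function(threshold = "sweep",
                            sweep_grid = seq(0, 0.9, by = 0.1),
                            min_votes = "auto", n_final = 50, r_max = 0.5,
                            prune_scope = "within-class",
                            second_pass_prune = FALSE,
                            use_embedded_svm = FALSE,
                            use_mrmr_union = FALSE, seed = 0) {
  if (is.numeric(threshold) && (threshold < 0 || threshold > 1))
    stopf("threshold must lie in [0, 1]")
  if (is.unsorted(sweep_grid)) stopf("sweep_grid must be ascending")
  if (n_final < 1) stopf("n_final must be >= 1")
  if (r_max <= 0 || r_max > 1) stopf("r_max must be in (0, 1]")
  structure(list(threshold = threshold, sweep_grid = sweep_grid,
                 min_votes = min_votes, n_final = as.integer(n_final),
                 r_max = r_max,
                 prune_scope = match.arg(prune_scope,
                                         c("within-class", "marginal")),
                 second_pass_prune = second_pass_prune,
                 use_embedded_svm = use_embedded_svm,
                 use_mrmr_union = use_mrmr_union, seed = as.integer(seed)),
            class = "selector_config")
}

#' Per-fold feature importances
#'
#' Fits the provider on the training side of each fold (all samples outside
#' the fold) and records its per-gene importances, giving a k x n_genes
#' table: k independent views of every gene's importance.
#'
#' @param matrix ExpressionMatrix.
#' @param folds [make_folds()] FoldSpec.
#' @param provider an importance provider, e.g. [gbt_provider()].
#' @return object of class `importance_table`: list with
#'   `fold_importances` (k x n_genes matrix), `fold_means`, `gene_ids`,
#'   `normalized` flag.
#' @export
fold_importances <- function(matrix, folds, provider = gbt_provider()) {
  k <- folds$k
  p <- length(matrix$gene_ids)
  imp <- matrix(0, k, p, dimnames = list(NULL, matrix$gene_ids))
  for (f in seq_len(k)) {
    tr <- folds$assignment != f
    row <- tryCatch(
      provider$importance(matrix$values[tr, , drop = FALSE],
                          matrix$labels[tr]),
      error = function(e) stopf("importance provider failed on fold %d: %s",
                                f, conditionMessage(e)))
    if (any(row < 0) || any(!is.finite(row)))
      stopf("provider returned negative or non-finite importances on fold %d", f)
    imp[f, ] <- row[matrix$gene_ids]
  }
  structure(list(fold_importances = imp, fold_means = rowMeans(imp),
                 gene_ids = matrix$gene_ids, normalized = FALSE),
            class = "importance_table")
}

#' Max-normalise an importance table
#'
#' Divides each fold row by its maximum so the threshold scale \[0, 1\] is
#' comparable across folds and providers; all-zero rows are left unchanged.
#' Idempotent.
#'
#' @param table [fold_importances()] output.
#' @return normalised `importance_table`.
#' @export
normalize_importances <- function(table) {
  imp <- table$fold_importances
  mx <- apply(imp, 1, max)
  nz <- mx > 0
  imp[nz, ] <- imp[nz, , drop = FALSE] / mx[nz]
  structure(list(fold_importances = imp, fold_means = rowMeans(imp),
                 gene_ids = table$gene_ids, normalized = TRUE),
            class = "importance_table")
}

#' Filter each fold's genes by an importance threshold
#'
#' @param table normalised [importance_table].
#' @param t threshold in \[0, 1\]; genes with importance strictly greater
#'   than `t` survive.
#' @return list of per-fold [gene_set()]s ordered by descending importance.
#' @export
threshold_filter <- function(table, t) {
  if (!isTRUE(table$normalized))
    stopf("threshold_filter requires a normalised importance table")
  if (t < 0 || t > 1) stopf("threshold %g outside [0, 1]", t)
  lapply(seq_len(nrow(table$fold_importances)), function(f) {
    row <- table$fold_importances[f, ]
    keep <- which(row > t)
    keep <- keep[order(-row[keep], table$gene_ids[keep])]
    gene_set(table$gene_ids[keep], row[keep])
  })
}

#' Count, per gene, the folds in which it survived the threshold
#'
#' @param fold_sets list of per-fold [gene_set()]s.
#' @return object of class `vote_tally`: named integer vector
#'   gene id -> number of folds containing it.
#' @export
vote <- function(fold_sets) {
  if (length(fold_sets) < 1) stopf("vote needs at least one fold set")
  ids <- unlist(lapply(fold_sets, `[[`, "gene_ids"))
  counts <- table(ids)
  structure(stats::setNames(as.integer(counts), names(counts)),
            class = "vote_tally", k = length(fold_sets))
}

resolve_min_votes <- function(min_votes, k) {
  if (identical(min_votes, "auto")) return(ceiling(0.75 * k))
  mv <- as.integer(min_votes)
  if (mv < 1 || mv > k) stopf("min_votes must lie in [1, k]")
  mv
}

#' Rank genes by votes and truncate to the final set size
#'
#' Genes are ordered by (votes desc, mean importance across folds desc,
#' gene id asc); genes below `min_votes` (or with zero votes) are dropped
#' and the result is truncated to `n_final`.
#'
#' @param tally [vote()] output.
#' @param table the [importance_table] the votes came from.
#' @param config [selector_config()].
#' @return [gene_set()]; scores are vote counts.
#' @export
select_by_votes <- function(tally, table, config = selector_config()) {
  k <- attr(tally, "k")
  mv <- resolve_min_votes(config$min_votes, k)
  ids <- names(tally)
  votes <- as.integer(tally)
  mean_imp <- colMeans(table$fold_importances)[ids]
  keep <- votes >= mv
  ids <- ids[keep]; votes <- votes[keep]; mean_imp <- mean_imp[keep]
  ord <- order(-votes, -mean_imp, ids)
  ord <- ord[seq_len(min(config$n_final, length(ord)))]
  gene_set(ids[ord], votes[ord])
}

#' Sweep the importance threshold for maximum CV accuracy
#'
#' For every grid point `t`: filter each fold at `t`, vote, rank-and-
#' truncate, then measure the cross-validated accuracy of the provider's
#' classifier restricted to the resulting genes. The selected threshold is
#' either the strict accuracy argmax (`rule = "max"`, smallest `t` on
#' exact ties) or, by default, the one-standard-error rule: the smallest
#' `t` whose mean accuracy is within one standard error (over folds) of
#' the best, which keeps the more inclusive gene set when the accuracy
#' curve is flat to within CV noise. A grid point whose selection is empty
#' is scored as majority-class accuracy.
#'
#' @inheritParams fold_importances
#' @param grid ascending thresholds in \[0, 1\].
#' @param config [selector_config()] (vote cutoff / final size used while
#'   scoring each grid point).
#' @param table optional precomputed normalised [importance_table].
#' @param rule `"1se"` (default) or `"max"`.
#' @return list with `best_t`, `curve` (data.frame of t, mean CV accuracy
#'   and its standard error) and `table` (the normalised importance
#'   table, reusable).
#' @export
sweep_threshold <- function(matrix, folds, provider = gbt_provider(),
                            grid = seq(0, 0.9, by = 0.1),
                            config = selector_config(), table = NULL,
                            rule = c("1se", "max")) {
  rule <- match.arg(rule)
  if (any(grid < 0 | grid > 1)) stopf("sweep grid must lie within [0, 1]")
  if (is.null(table))
    table <- normalize_importances(fold_importances(matrix, folds, provider))
  scores <- lapply(grid, function(t) {
    sel <- select_by_votes(vote(threshold_filter(table, t)), table, config)
    if (length(sel) == 0) {
      return(c(mean = max(table(matrix$labels)) / length(matrix$labels),
               se = 0))
    }
    sub <- subset_matrix(matrix, genes = sel$gene_ids)
    acc <- cv_fold_accuracy(sub, folds, provider)
    c(mean = mean(acc), se = stats::sd(acc) / sqrt(length(acc)))
  })
  acc <- vapply(scores, `[[`, numeric(1), "mean")
  se <- vapply(scores, `[[`, numeric(1), "se")
  i_max <- which.max(acc) # first (smallest t) on exact ties
  best_t <- if (rule == "max") grid[i_max] else
    grid[which(acc >= acc[i_max] - se[i_max])[1]]
  list(best_t = best_t,
       curve = data.frame(t = grid, accuracy = acc, se = se),
       table = table)
}

# per-fold held-out accuracy of the provider's classifier
cv_fold_accuracy <- function(matrix, folds, provider) {
  vapply(seq_len(folds$k), function(f) {
    te <- folds$assignment == f
    pred <- provider$classify(matrix$values[!te, , drop = FALSE],
                              matrix$labels[!te],
                              matrix$values[te, , drop = FALSE])
    mean(pred == matrix$labels[te])
  }, numeric(1))
}

#' Rank genes by absolute linear-SVM weight
#'
#' Fits a linear maximum-margin classifier and ranks genes by the absolute
#' value of their weight in the primal hyperplane; ties broken by gene id.
#'
#' @param matrix ExpressionMatrix (two classes present).
#' @param top_m number of top-ranked genes to return.
#' @return [gene_set()] of the `top_m` genes, scores = |weight|.
#' @export
embedded_svm_rank <- function(matrix, top_m = length(matrix$gene_ids)) {
  if (length(unique(matrix$labels)) < 2)
    stopf("embedded_svm_rank needs two classes")
  top_m <- min(top_m, length(matrix$gene_ids))
  fit <- tryCatch(
    e1071::svm(matrix$values, factor(matrix$labels), kernel = "linear",
               scale = FALSE),
    error = function(e) stopf("linear SVM fit failed: %s", conditionMessage(e)))
  w <- abs(as.numeric(t(fit$coefs) %*% fit$SV))
  names(w) <- colnames(fit$SV)
  w <- w[matrix$gene_ids]
  ord <- order(-w, matrix$gene_ids)[seq_len(top_m)]
  gene_set(matrix$gene_ids[ord], unname(w[ord]))
}

#' Merge gene sets, keeping unique genes
#'
#' Concatenates the sets, applies a seeded shuffle, and keeps the first
#' occurrence of each gene, so the merge order is reproducible but carries
#' no per-set precedence.
#'
#' @param sets list of [gene_set()]s.
#' @param seed integer shuffle seed.
#' @return merged [gene_set()].
#' @export
merge_unique <- function(sets, seed = 0) {
  ids <- unlist(lapply(sets, `[[`, "gene_ids"))
  scores <- unlist(lapply(sets, `[[`, "scores"))
  if (length(ids) == 0) return(gene_set(character(0), numeric(0)))
  perm <- with_seed(seed, sample.int(length(ids)))
  ids <- ids[perm]; scores <- scores[perm]
  keep <- !duplicated(ids)
  gene_set(ids[keep], scores[keep])
}

#' Greedy correlation-redundancy pruning
#'
#' Scans the genes in set order; a gene is dropped if its absolute Pearson
#' correlation with any already-kept gene reaches `r_max`. Constant genes
#' correlate 0 with everything and are kept. The kept set therefore has
#' all pairwise `|r| < r_max` on the scope used.
#'
#' With the default `"within-class"` scope each gene is centred on its
#' class means before correlating, so the measured correlation reflects
#' shared information beyond the class effect. Two independent but
#' strongly predictive markers are *marginally* correlated purely because
#' both track the label (at class-mean shift `e` and balanced classes the
#' induced correlation is `e^2/4 / (1 + e^2/4)`, i.e. 0.5 already at
#' `e = 2`); such complementary markers are redundant only if they remain
#' correlated within class. `"marginal"` applies the plain Pearson rule on
#' the raw values.
#'
#' @param matrix ExpressionMatrix containing the genes.
#' @param genes [gene_set()] in priority order.
#' @param r_max drop cutoff in (0, 1].
#' @param scope `"within-class"` (default) or `"marginal"`.
#' @return pruned [gene_set()].
#' @export
correlation_prune <- function(matrix, genes, r_max = 0.5,
                              scope = c("within-class", "marginal")) {
  scope <- match.arg(scope)
  if (!all(genes$gene_ids %in% matrix$gene_ids))
    stopf("genes not present in matrix: %s",
          paste(setdiff(genes$gene_ids, matrix$gene_ids), collapse = ", "))
  kept <- integer(0)
  vals <- matrix$values[, genes$gene_ids, drop = FALSE]
  if (scope == "within-class") vals <- center_by_class(vals, matrix$labels)
  for (i in seq_along(genes$gene_ids)) {
    redundant <- FALSE
    for (j in kept) {
      if (abs(safe_cor(vals[, i], vals[, j])) >= r_max) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  gene_set(genes$gene_ids[kept], genes$scores[kept])
}

#' Build a per-training-fold gene selector for nested cross-validation
#'
#' Wraps the selection flow as a `function(train_matrix)` suitable for
#' [cross_validate()]'s `selector` argument, so selection is re-run inside
#' every training fold and the held-out fold never informs it. The
#' threshold must be numeric here (an accuracy sweep inside every outer
#' fold would nest three CV levels).
#'
#' @param k inner folds used for the importance table.
#' @param config [selector_config()] with a numeric `threshold`.
#' @param provider importance provider; default [gbt_provider()] seeded
#'   from `config$seed`.
#' @return function(ExpressionMatrix) -> [gene_set()].
#' @export
make_nested_selector <- function(k = 8, config = selector_config(threshold = 0),
                                 provider = NULL) {
  if (!is.numeric(config$threshold))
    stopf("nested selection needs a numeric threshold")
  if (is.null(provider)) provider <- gbt_provider(seed = config$seed)
  function(train) {
    inner_k <- min(k, length(train$labels))
    folds <- make_folds(train$labels, inner_k, seed = config$seed)
    scaled <- scale_minmax(train)
    select_genes(scaled, folds, config, provider = provider)$genes
  }
}

# subtract each gene's class-conditional mean
center_by_class <- function(vals, labels) {
  for (cl in unique(labels)) {
    i <- labels == cl
    vals[i, ] <- sweep(vals[i, , drop = FALSE], 2,
                       colMeans(vals[i, , drop = FALSE]))
  }
  vals
}

#' Run the full hybrid gene-selection flow
#'
#' Orchestrates the selection stages: per-fold importances from the
#' provider, max-normalisation, threshold filter (fixed or accuracy-swept),
#' cross-fold voting with rank-and-truncate, optional per-fold embedded-SVM
#' ranking and mRMR-ensemble union, and correlation pruning.
#'
#' @param matrix ExpressionMatrix (already scaled; see [scale_minmax()]).
#' @param folds FoldSpec.
#' @param config [selector_config()].
#' @param provider importance provider; default [gbt_provider()] seeded
#'   from `config$seed`.
#' @param mrmr_cfg [mrmr_config()] used when `use_mrmr_union` is on.
#' @return list with `genes` (final [gene_set()]), `threshold` (the
#'   threshold used), `sweep_curve` (or NULL), `table` (normalised
#'   importance table), `tally` and `stage_counts` (per-stage gene counts:
#'   non-zero per fold, SVM redundant/unique, post-vote, post-prune).
#' @export
select_genes <- function(matrix, folds, config = selector_config(),
                         provider = NULL, mrmr_cfg = mrmr_config()) {
  if (is.null(provider)) provider <- gbt_provider(seed = config$seed)
  table <- normalize_importances(fold_importances(matrix, folds, provider))
  sweep_curve <- NULL
  if (identical(config$threshold, "sweep")) {
    sw <- sweep_threshold(matrix, folds, provider, config$sweep_grid,
                          config, table = table)
    t_use <- sw$best_t
    sweep_curve <- sw$curve
  } else {
    t_use <- config$threshold
  }
  fold_sets <- threshold_filter(table, t_use)
  tally <- vote(fold_sets)
  voted <- select_by_votes(tally, table, config)
  stage_counts <- list(
    nonzero_per_fold = as.integer(rowSums(table$fold_importances > 0)),
    above_threshold_per_fold = vapply(fold_sets, length, integer(1)),
    post_vote = length(voted))
  candidates <- voted
  if (isTRUE(config$use_embedded_svm)) {
    svm_sets <- lapply(seq_len(folds$k), function(f) {
      embedded_svm_rank(subset_matrix(matrix,
                                      samples = folds$assignment != f))
    })
    stage_counts$svm_redundant <- sum(vapply(svm_sets, length, integer(1)))
    svm_unique <- merge_unique(svm_sets, seed = config$seed)
    stage_counts$svm_unique <- length(svm_unique)
    candidates <- merge_unique(list(candidates, svm_unique),
                               seed = config$seed)
  }
  if (isTRUE(config$use_mrmr_union)) {
    sols <- mrmr_exhaustive(matrix, mrmr_cfg,
                            k_starts = min(5, length(matrix$gene_ids)))
    candidates <- merge_unique(c(list(candidates), sols),
                               seed = config$seed)
  }
  pruned <- correlation_prune(matrix, candidates, config$r_max,
                              scope = config$prune_scope)
  if (isTRUE(config$second_pass_prune))
    pruned <- correlation_prune(matrix, pruned, min(1, config$r_max + 0.01),
                                scope = config$prune_scope)
  stage_counts$post_prune <- length(pruned)
  list(genes = pruned, threshold = t_use, sweep_curve = sweep_curve,
       table = table, tally = tally, stage_counts = stage_counts)
}
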