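# Importance-provider contract: an object that, fitted on a training
# matrix and labels, emits one non-negative importance per gene.

#' Gradient-boosted-tree importance provider
#'
#' The default feature-importance engine: a boosted classification-tree
#' ensemble whose per-gene split-gain totals serve as importances. The
#' low learning rate and per-tree column subsampling decorrelate the trees
#' so informative genes that shadow each other in a single greedy tree all
#' accumulate gain. Genes never used by any tree score 0.
#'
#' @param nrounds number of boosting rounds.
#' @param max_depth tree depth.
#' @param learning_rate shrinkage per round.
#' @param colsample fraction of genes sampled per tree.
#' @param seed integer seed for the booster's internal RNG.
#' @return object of class `importance_provider` with elements `importance`
#'   (function(values, labels) -> named non-negative vector), `classify`
#'   (function(train_values, train_labels, test_values) -> 0/1 predictions)
#'   and `label`.
#' @export
gbt_provider <- function(nrounds = 150, max_depth = 3, learning_rate = 0.1,
                         colsample = 0.5, seed = 0) {
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = learning_rate, colsample_bytree = colsample,
                 nthread = 1, seed = as.integer(seed))
  fit <- function(values, labels) {
    dm <- xgboost::xgb.DMatrix(values, label = labels, nthread = 1)
    xgboost::xgb.train(params, dm, nrounds = nrounds, verbose = 0)
  }
  structure(list(
    label = "gradient-boosted trees",
    importance = function(values, labels) {
      bst <- fit(values, labels)
      imp <- xgboost::xgb.importance(model = bst)
      out <- stats::setNames(rep(0, ncol(values)), colnames(values))
      out[imp$Feature] <- imp$Gain
      out
    },
    classify = function(train_values, train_labels, test_values) {
      bst <- fit(train_values, train_labels)
      p <- stats::predict(bst, xgboost::xgb.DMatrix(test_values, nthread = 1))
      as.integer(p > 0.5)
    }),
    class = "importance_provider")
}

#' t-statistic importance provider
#'
#' A deterministic, closed-form provider: each gene's importance is the
#' absolute two-sample t statistic of its class difference, and
#' classification is by nearest class centroid over all genes. Useful for
#' fast, exactly reproducible runs and as a reference provider in tests.
#'
#' @return `importance_provider` object; see [gbt_provider()].
#' @export
tstat_provider <- function() {
  structure(list(
    label = "absolute two-sample t statistic",
    importance = function(values, labels) {
      i1 <- labels == 1
      n1 <- sum(i1); n0 <- sum(!i1)
      m1 <- colMeans(values[i1, , drop = FALSE])
      m0 <- colMeans(values[!i1, , drop = FALSE])
      v1 <- apply(values[i1, , drop = FALSE], 2, stats::var)
      v0 <- apply(values[!i1, , drop = FALSE], 2, stats::var)
      se <- sqrt(v1 / n1 + v0 / n0)
      out <- abs(m1 - m0) / pmax(se, .Machine$double.eps)
      out[se == 0 & m1 == m0] <- 0
      stats::setNames(out, colnames(values))
    },
    classify = function(train_values, train_labels, test_values) {
      c1 <- colMeans(train_values[train_labels == 1, , drop = FALSE])
      c0 <- colMeans(train_values[train_labels == 0, , drop = FALSE])
      d1 <- rowSums(sweep(test_values, 2, c1)^2)
      d0 <- rowSums(sweep(test_values, 2, c0)^2)
      as.integer(d1 < d0)
    }),
    class = "importance_provider")
}
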