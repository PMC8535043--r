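# Shared fixtures: tiny matrices, a deterministic stub provider, and an
# independent brute-force mRMR oracle used to cross-check the greedy path.

# small ExpressionMatrix from an explicit value matrix
tiny_matrix <- function(values, labels, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, gene_ids = gene_ids,
                    sample_ids = sprintf("s%02d", seq_len(nrow(values))),
                    labels = labels)
}

# random two-class instance for oracle comparisons
random_instance <- function(seed, n = 20, p = 8) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p)
  y <- rep(0:1, length.out = n)
  v[y == 1, 1] <- v[y == 1, 1] + 1.5
  tiny_matrix(v, y)
}

# provider whose importances are a fixed function of the data: row f gets
# per-gene |class-mean difference| (deterministic, no fitting)
stub_provider <- function() {
  structure(list(
    label = "class-mean difference stub",
    importance = function(values, labels) {
      d <- abs(colMeans(values[labels == 1, , drop = FALSE]) -
                 colMeans(values[labels == 0, , drop = FALSE]))
      stats::setNames(d, colnames(values))
    },
    classify = function(xtr, ytr, xte) {
      c1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
      c0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
      as.integer(rowSums(sweep(xte, 2, c1)^2) < rowSums(sweep(xte, 2, c0)^2))
    }),
    class = "importance_provider")
}

# constant-importance provider: every gene equally important
flat_provider <- function() {
  structure(list(
    label = "flat stub",
    importance = function(values, labels) {
      stats::setNames(rep(1, ncol(values)), colnames(values))
    },
    classify = function(xtr, ytr, xte) {
      rep(as.integer(mean(ytr) > 0.5), nrow(xte))
    }),
    class = "importance_provider")
}

# Independent brute-force mRMR: re-evaluates the greedy criterion over all
# candidates at each step with direct cor() calls (no shared code with
# mrmr_rank's incremental bookkeeping).
brute_mrmr <- function(matrix, config) {
  brute_mrmr_forced(matrix, config, NULL)
}

# same oracle with the first gene forced (exhaustive-ensemble check)
brute_mrmr_forced <- function(matrix, config, head) {
  ids <- matrix$gene_ids
  v <- matrix$values
  y <- matrix$labels
  rel <- vapply(seq_along(ids), function(j) {
    if (sd(v[, j]) == 0) return(0)
    abs(cor(v[, j], y))
  }, numeric(1))
  selected <- character(0)
  if (!is.null(head)) selected <- head
  for (step in seq_len(config$m - length(selected))) {
    best_id <- NA_character_
    best_crit <- -Inf
    for (j in seq_along(ids)) {
      if (ids[j] %in% selected) next
      if (length(selected) == 0) {
        crit <- rel[j]
      } else {
        red <- mean(vapply(selected, function(s) {
          sj <- match(s, ids)
          if (sd(v[, j]) == 0 || sd(v[, sj]) == 0) return(0)
          abs(cor(v[, j], v[, sj]))
        }, numeric(1)))
        crit <- switch(config$scheme,
                       quotient = rel[j] / max(red, config$epsilon),
                       difference = rel[j] - red)
      }
      tol <- if (is.finite(best_crit)) 1e-12 * max(1, abs(best_crit)) else 0
      if (is.na(best_id) || crit > best_crit + tol ||
          (abs(crit - best_crit) <= tol && ids[j] < best_id)) {
        best_crit <- crit
        best_id <- ids[j]
      }
    }
    selected <- c(selected, best_id)
  }
  selected
}
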