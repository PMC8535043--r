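# Classic greedy mRMR ranking and its exhaustive / bootstrap ensembles.

#' Construct an ordered gene set
#'
#' @param gene_ids character vector in selection order, no duplicates.
#' @param scores parallel numeric vector of selection-time scores.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(gene_ids, scores = rep(NA_real_, length(gene_ids))) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stopf("gene_set ids contain duplicates: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(scores) != length(gene_ids))
    stopf("scores length %d != %d gene ids", length(scores), length(gene_ids))
  structure(list(gene_ids = gene_ids, scores = as.numeric(scores)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set of %d genes\n", length(x$gene_ids)))
  n <- min(10, length(x$gene_ids))
  if (n > 0)
    print(utils::head(data.frame(rank = seq_along(x$gene_ids),
                                 gene_id = x$gene_ids, score = x$scores), n))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$gene_ids)

#' @export
as.data.frame.gene_set <- function(x, ...) {
  data.frame(rank = seq_along(x$gene_ids), gene_id = x$gene_ids,
             score = x$scores, stringsAsFactors = FALSE)
}

#' mRMR configuration
#'
#' @param m target number of genes to select.
#' @param scheme greedy criterion combining relevance `rel` and mean
#'   redundancy `red` to the already-selected set: `"quotient"`
#'   (`rel / max(red, epsilon)`, the default) or `"difference"`
#'   (`rel - red`).
#' @param relevance_metric `"abs-pearson-with-label"` (default,
#'   point-biserial |r| against the 0/1 label) or `"f-statistic"`
#'   (two-group ANOVA F).
#' @param epsilon floor for the quotient denominator.
#' @return object of class `mrmr_config`.
#' @export
mrmr_config <- function(m = 50, scheme = c("quotient", "difference"),
                        relevance_metric = c("abs-pearson-with-label",
                                             "f-statistic"),
                        epsilon = 1e-6) {
  if (m < 1) stopf("m must be >= 1")
  if (epsilon <= 0) stopf("epsilon must be positive")
  structure(list(m = as.integer(m), scheme = match.arg(scheme),
                 relevance_metric = match.arg(relevance_metric),
                 epsilon = epsilon),
            class = "mrmr_config")
}

#' Per-gene relevance to the class label
#'
#' @param matrix ExpressionMatrix with both classes present.
#' @param config [mrmr_config()].
#' @return named non-negative numeric vector, one score per gene.
#' @export
relevance <- function(matrix, config = mrmr_config()) {
  y <- matrix$labels
  if (length(unique(y)) < 2)
    stopf("relevance needs two classes; labels are single-class")
  v <- matrix$values
  scores <- switch(config$relevance_metric,
    "abs-pearson-with-label" = abs(apply(v, 2, safe_cor, y = y)),
    "f-statistic" = {
      n1 <- sum(y == 1); n0 <- sum(y == 0)
      m1 <- colMeans(v[y == 1, , drop = FALSE])
      m0 <- colMeans(v[y == 0, , drop = FALSE])
      gm <- colMeans(v)
      ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
      ssw <- colSums((v[y == 1, , drop = FALSE] -
                        rep(m1, each = n1))^2) +
             colSums((v[y == 0, , drop = FALSE] -
                        rep(m0, each = n0))^2)
      f <- ssb / (pmax(ssw, .Machine$double.eps) / (n1 + n0 - 2))
      f[ssw == 0 & ssb == 0] <- 0
      f
    })
  stats::setNames(as.numeric(scores), matrix$gene_ids)
}

# pick the maximising index with ties broken by ascending gene id
argmax_by_id <- function(scores, ids) {
  best <- max(scores)
  cand <- which(scores >= best - 1e-12 * max(1, abs(best)))
  cand[order(ids[cand])][1]
}

mrmr_greedy <- function(values, rel, config, first = NULL) {
  ids <- names(rel)
  m <- config$m
  selected <- integer(0)
  sel_scores <- numeric(0)
  red_sum <- numeric(length(rel)) # running sum of |r| to selected genes
  for (step in seq_len(m)) {
    if (step == 1 && !is.null(first)) {
      pick <- first
      crit <- rel
    } else if (length(selected) == 0) {
      crit <- rel
      pick <- argmax_by_id(crit, ids)
    } else {
      red <- red_sum / length(selected)
      crit <- switch(config$scheme,
                     quotient = rel / pmax(red, config$epsilon),
                     difference = rel - red)
      crit[selected] <- -Inf
      pick <- argmax_by_id(crit, ids)
    }
    selected <- c(selected, pick)
    sel_scores <- c(sel_scores, crit[pick])
    if (length(selected) < m) {
      r_new <- abs(apply(values, 2, safe_cor, y = values[, pick]))
      red_sum <- red_sum + r_new
    }
  }
  gene_set(ids[selected], sel_scores)
}

#' Greedy mRMR gene ranking
#'
#' Selects `m` genes: the first is the relevance argmax; each subsequent
#' gene maximises the configured scheme applied to its relevance and its
#' mean absolute Pearson correlation with the already-selected set. Ties
#' are broken by ascending gene id.
#'
#' @inheritParams relevance
#' @return [gene_set()] of length `config$m` in selection order; scores are
#'   the criterion values at selection time.
#' @export
mrmr_rank <- function(matrix, config = mrmr_config()) {
  if (config$m > length(matrix$gene_ids))
    stopf("m = %d exceeds the %d available genes", config$m,
          length(matrix$gene_ids))
  rel <- relevance(matrix, config)
  mrmr_greedy(matrix$values, rel, config)
}

#' Exhaustive ensemble mRMR
#'
#' Runs `k_starts` greedy selections in parallel conceptually, the i-th
#' forced to start from the i-th most relevant gene, so the first selected
#' gene of every solution is distinct.
#'
#' @inheritParams relevance
#' @param k_starts number of solutions, `<= n_genes`.
#' @return list of `k_starts` [gene_set()] objects.
#' @export
mrmr_exhaustive <- function(matrix, config = mrmr_config(), k_starts = 5) {
  p <- length(matrix$gene_ids)
  if (k_starts > p)
    stopf("k_starts = %d exceeds the %d available genes", k_starts, p)
  if (config$m > p)
    stopf("m = %d exceeds the %d available genes", config$m, p)
  rel <- relevance(matrix, config)
  heads <- order(-rel, matrix$gene_ids)[seq_len(k_starts)]
  lapply(heads, function(h) mrmr_greedy(matrix$values, rel, config, first = h))
}

#' Bootstrap ensemble mRMR
#'
#' Draws `k_boot` stratified bootstrap resamples of the samples (with
#' replacement, class counts preserved) and runs classic mRMR on each.
#'
#' @inheritParams relevance
#' @param k_boot number of bootstrap solutions.
#' @param seed integer seed; the same seed reproduces the resamples.
#' @return list of `k_boot` [gene_set()] objects.
#' @export
mrmr_bootstrap <- function(matrix, config = mrmr_config(), k_boot = 5,
                           seed = 0) {
  if (k_boot < 1) stopf("k_boot must be >= 1")
  y <- matrix$labels
  resamples <- with_seed(seed, {
    lapply(seq_len(k_boot), function(b) {
      unlist(lapply(sort(unique(y)), function(cl) {
        idx <- which(y == cl)
        idx[sample.int(length(idx), length(idx), replace = TRUE)]
      }))
    })
  })
  lapply(resamples, function(idx) {
    mrmr_rank(subset_matrix(matrix, samples = idx), config)
  })
}
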