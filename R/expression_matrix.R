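# ExpressionMatrix container and delimited-text I/O.

#' Construct an ExpressionMatrix
#'
#' The container every pipeline stage consumes: a samples x genes numeric
#' matrix plus a binary class label per sample (0 = healthy/class A,
#' 1 = cancer/class B).
#'
#' @param values numeric matrix, samples as rows, genes as columns.
#' @param gene_ids character vector of unique gene/probe-set identifiers,
#'   one per column. Defaults to `colnames(values)`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row. Defaults to `rownames(values)`.
#' @param labels vector with at most two distinct values; recoded to 0/1.
#' @param positive_label optional; the label value mapped to 1. By default
#'   the larger of the two sorted observed values becomes 1.
#' @return object of class `ExpressionMatrix`: list with elements `values`
#'   (matrix with dimnames), `gene_ids`, `sample_ids`, `labels` (integer 0/1).
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              sample_ids = rownames(values), labels,
                              positive_label = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d_at", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != ncol(values))
    stopf("gene_ids length %d != %d genes", length(gene_ids), ncol(values))
  if (length(sample_ids) != nrow(values))
    stopf("sample_ids length %d != %d samples", length(sample_ids), nrow(values))
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stopf("duplicate gene ids: %s", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stopf("duplicate sample ids: %s", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stopf("expression values contain %d non-finite entries", sum(!is.finite(values)))
  if (length(labels) != nrow(values))
    stopf("labels length %d != %d samples", length(labels), nrow(values))
  lv <- sort(unique(labels))
  if (length(lv) > 2)
    stopf("labels have %d distinct values (%s); at most two allowed",
          length(lv), paste(lv, collapse = ", "))
  if (!is.null(positive_label)) {
    if (length(lv) == 2 && !positive_label %in% lv)
      stopf("positive_label '%s' not among observed labels", positive_label)
    labels <- as.integer(labels == positive_label)
  } else {
    labels <- as.integer(labels == lv[length(lv)])
    if (length(lv) == 1) labels <- rep(0L, length(labels))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d samples x %d genes (class 1: %d, class 0: %d)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by samples and/or genes
#'
#' @param m ExpressionMatrix.
#' @param samples integer/logical/character index of samples to keep.
#' @param genes integer/logical/character index of genes to keep.
#' @return ExpressionMatrix restricted to the requested rows/columns.
#' @export
subset_matrix <- function(m, samples = NULL, genes = NULL) {
  v <- m$values
  lab <- m$labels
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, m$sample_ids)
    v <- v[samples, , drop = FALSE]
    lab <- lab[samples]
    # resampling with replacement (bootstrap) may repeat samples
    rownames(v) <- make.unique(rownames(v))
  }
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, m$gene_ids)
    v <- v[, genes, drop = FALSE]
  }
  expression_matrix(v, labels = lab, positive_label = 1)
}

parse_dialect <- function(dialect) {
  dialect <- match.arg(dialect, c("tsv", "csv", "gct"))
  list(sep = if (dialect == "csv") "," else "\t", dialect = dialect)
}

#' Read an expression matrix from delimited text
#'
#' Supports plain CSV/TSV (header row of gene ids, first column the sample
#' id, labels in a named column or -- for genes-as-rows files -- a named
#' row) and a GCT-like dialect (two header lines, then NAME/Description
#' columns with genes as rows and a label row named by `label_column`).
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"csv"`, `"gct"`.
#' @param orientation `"samples-as-rows"` (default for csv/tsv) or
#'   `"genes-as-rows"` (forced for gct).
#' @param label_column name of the label column (or label row when genes
#'   are rows). Default `"label"`.
#' @param positive_label optional label value to encode as 1.
#' @return [expression_matrix()] object, orientation normalised to
#'   samples-as-rows.
#' @export
read_matrix <- function(path, dialect = "tsv",
                        orientation = c("samples-as-rows", "genes-as-rows"),
                        label_column = "label", positive_label = NULL) {
  d <- parse_dialect(dialect)
  orientation <- match.arg(orientation)
  if (d$dialect == "gct") {
    raw <- utils::read.delim(path, sep = "\t", skip = 2, header = TRUE,
                             check.names = FALSE, colClasses = "character")
    rown <- raw[[1]]
    body <- raw[, -(1:2), drop = FALSE]  # drop NAME, Description
    orientation <- "genes-as-rows"
  } else {
    # read.delim silently uniquifies duplicate header names; check them raw
    hdr <- strsplit(readLines(path, n = 1), d$sep, fixed = TRUE)[[1]][-1]
    dup <- unique(hdr[duplicated(hdr)])
    if (length(dup))
      stopf("duplicate ids in %s header: %s", path, paste(dup, collapse = ", "))
    raw <- utils::read.delim(path, sep = d$sep, header = TRUE,
                             check.names = FALSE, colClasses = "character")
    rown <- raw[[1]]
    body <- raw[, -1, drop = FALSE]
  }
  if (orientation == "samples-as-rows") {
    if (!label_column %in% colnames(body))
      stopf("label column '%s' not found in %s", label_column, path)
    labels <- body[[label_column]]
    body <- body[, setdiff(colnames(body), label_column), drop = FALSE]
    sample_ids <- rown
    gene_ids <- colnames(body)
    vals <- char_to_numeric(body, rown, colnames(body), path)
  } else {
    if (!label_column %in% rown)
      stopf("label row '%s' not found in %s", label_column, path)
    lab_i <- which(rown == label_column)
    labels <- as.character(unlist(body[lab_i[1], ]))
    body <- body[-lab_i, , drop = FALSE]
    gene_ids <- rown[-lab_i]
    sample_ids <- colnames(body)
    vals <- t(char_to_numeric(body, gene_ids, colnames(body), path))
  }
  lab_num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(lab_num)) labels <- lab_num
  rownames(vals) <- sample_ids
  colnames(vals) <- gene_ids
  expression_matrix(vals, labels = labels, positive_label = positive_label)
}

# parse a character data.frame, reporting the coordinates of bad cells
char_to_numeric <- function(df, row_ids, col_ids, path) {
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA")
    if (length(bad))
      stopf("non-numeric cell '%s' at row '%s', column '%s' in %s",
            df[[j]][bad[1]], row_ids[bad[1]], col_ids[j], path)
    m[, j] <- v
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("missing value at row '%s', column '%s' in %s",
          row_ids[idx[1]], col_ids[idx[2]], path)
  }
  m
}

#' Write an ExpressionMatrix to delimited text
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(m))` recovers `m`
#' up to 12 significant digits.
#'
#' @param m ExpressionMatrix.
#' @param path output file path.
#' @param dialect one of `"tsv"`, `"csv"`, `"gct"`.
#' @param label_column name used for the label column/row.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, dialect = "tsv", label_column = "label") {
  d <- parse_dialect(dialect)
  fmt <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  if (d$dialect == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", sprintf("%d\t%d", length(m$gene_ids), length(m$sample_ids))), con)
    writeLines(paste(c("NAME", "Description", m$sample_ids), collapse = "\t"), con)
    writeLines(paste(c(label_column, "class label", fmt(m$labels)), collapse = "\t"), con)
    tv <- t(m$values)
    for (i in seq_len(nrow(tv))) {
      writeLines(paste(c(m$gene_ids[i], "", fmt(tv[i, ])), collapse = "\t"), con)
    }
  } else {
    df <- data.frame(sample_id = m$sample_ids, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df[[label_column]] <- m$labels
    vals <- as.data.frame(apply(m$values, 2, fmt), stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (nrow(m$values) == 1) { # apply() drops to a vector for one row
      vals <- as.data.frame(as.list(fmt(m$values[1, ])), check.names = FALSE)
      colnames(vals) <- m$gene_ids
    }
    df <- cbind(df, vals)
    utils::write.table(df, path, sep = d$sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Min-max scale genes to [0, 1] using training-set statistics
#'
#' Each gene is mapped to `(x - min_train) / (max_train - min_train)` so the
#' training matrix lies in \[0, 1\]; applied-to values outside the training
#' range are NOT clipped and may fall outside \[0, 1\]. A gene constant on
#' the training set maps to all zeros.
#'
#' @param train ExpressionMatrix the ranges are fitted on.
#' @param apply_to ExpressionMatrix the transform is applied to (same genes
#'   as `train`); defaults to `train`.
#' @return scaled ExpressionMatrix with `apply_to`'s samples and labels.
#' @export
scale_minmax <- function(train, apply_to = train) {
  if (!identical(train$gene_ids, apply_to$gene_ids))
    stopf("apply_to gene ids differ from train gene ids")
  mins <- apply(train$values, 2, min)
  maxs <- apply(train$values, 2, max)
  rng <- maxs - mins
  const <- rng == 0
  rng[const] <- 1
  v <- sweep(sweep(apply_to$values, 2, mins, "-"), 2, rng, "/")
  v[, const] <- 0
  expression_matrix(v, gene_ids = apply_to$gene_ids,
                    sample_ids = apply_to$sample_ids,
                    labels = apply_to$labels, positive_label = 1)
}

#' Build stratified k-fold assignments
#'
#' Samples are shuffled within each class under `seed` and dealt round-robin
#' across folds, continuing the deal between classes so fold sizes differ by
#' at most one and per-fold class counts stay within one of proportional.
#'
#' @param labels binary label vector.
#' @param k number of folds, `2 <= k <= length(labels)`.
#' @param seed integer seed controlling the shuffle.
#' @return object of class `FoldSpec`: list with `k`, `seed` and
#'   `assignment`, an integer vector in `1..k` parallel to `labels`.
#' @export
make_folds <- function(labels, k, seed = 0) {
  n <- length(labels)
  if (k < 2) stopf("k must be at least 2 (got %d)", k)
  if (k > n) stopf("k = %d exceeds the %d available samples", k, n)
  assignment <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "FoldSpec")
}

#' @export
print.FoldSpec <- function(x, ...) {
  cat(sprintf("FoldSpec: k = %d, fold sizes %s (seed %d)\n", x$k,
              paste(tabulate(x$assignment, x$k), collapse = "/"), x$seed))
  invisible(x)
}

#' Write a FoldSpec as two-column TSV (sample_id, fold)
#' @param folds FoldSpec.
#' @param sample_ids sample identifiers parallel to the assignment.
#' @param path output path.
#' @export
write_folds <- function(folds, sample_ids, path) {
  utils::write.table(
    data.frame(sample_id = sample_ids, fold = folds$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
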