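sim60 <- function(seed) {
  generate_dataset(simulation_spec(
    n_samples = 60, n_genes = 120, n_informative = 5,
    n_redundant_per_informative = 0, effect_size = 2, seed = seed))
}

test_that("fold importances have one provider row per fold", {
  ds <- sim60(1)
  folds <- make_folds(ds$matrix$labels, 4, seed = 1)
  tab <- fold_importances(ds$matrix, folds, stub_provider())
  expect_equal(dim(tab$fold_importances), c(4, 120))
  expect_true(all(tab$fold_importances >= 0))
  expect_false(tab$normalized)
  # each row reproduces the stub fitted on the fold's training side
  f2 <- folds$assignment != 2
  exp_row <- stub_provider()$importance(ds$matrix$values[f2, ],
                                        ds$matrix$labels[f2])
  expect_equal(unname(tab$fold_importances[2, ]), unname(exp_row))

  bad <- structure(list(importance = function(v, l) stop("boom")),
                   class = "importance_provider")
  expect_error(fold_importances(ds$matrix, folds, bad), "fold 1")
})

test_that("normalisation is per-fold max and idempotent", {
  tab <- structure(list(
    fold_importances = rbind(c(2, 4, 8), c(0, 0, 0)),
    fold_means = c(14 / 3, 0), gene_ids = c("a", "b", "c"),
    normalized = FALSE), class = "importance_table")
  nt <- normalize_importances(tab)
  expect_equal(unname(nt$fold_importances[1, ]), c(0.25, 0.5, 1))
  expect_equal(unname(nt$fold_importances[2, ]), c(0, 0, 0)) # all-zero row
  expect_true(nt$normalized)
  expect_equal(normalize_importances(nt)$fold_importances,
               nt$fold_importances)
})

test_that("threshold filtering is strict and ordered by importance", {
  tab <- structure(list(
    fold_importances = rbind(c(0.9, 0.5, 0.84)), fold_means = NA,
    gene_ids = c("g1", "g2", "g3"), normalized = TRUE),
    class = "importance_table")
  sets <- threshold_filter(tab, 0.84)
  expect_identical(sets[[1]]$gene_ids, "g1")  # 0.84 itself excluded
  expect_identical(threshold_filter(tab, 0)[[1]]$gene_ids,
                   c("g1", "g3", "g2"))
  expect_length(threshold_filter(tab, 1)[[1]], 0)
  expect_error(threshold_filter(tab, 1.2), "outside")
  raw <- structure(list(fold_importances = rbind(c(2, 1, 1)),
                        gene_ids = tab$gene_ids, normalized = FALSE),
                   class = "importance_table")
  expect_error(threshold_filter(raw, 0.5), "normalised")
})

test_that("flat importances survive any threshold below one", {
  ds <- sim60(2)
  folds <- make_folds(ds$matrix$labels, 4, seed = 1)
  tab <- normalize_importances(fold_importances(ds$matrix, folds,
                                                flat_provider()))
  sets <- threshold_filter(tab, 0.99)
  expect_true(all(vapply(sets, length, integer(1)) == 120))
})

test_that("voting counts fold membership", {
  sets <- list(gene_set(c("A", "B")), gene_set("A"), gene_set(c("A", "C")))
  tally <- vote(sets)
  expect_equal(tally[["A"]], 3)
  expect_equal(tally[["B"]], 1)
  expect_equal(tally[["C"]], 1)
  expect_equal(attr(tally, "k"), 3)
  expect_error(vote(list()), "at least one")
})

test_that("select_by_votes orders by votes, importance, then id", {
  tab <- structure(list(
    fold_importances = rbind(c(1, 0.8, 0.8, 0.2), c(1, 0.8, 0.8, 0.2)),
    gene_ids = c("gD", "gB", "gA", "gC"), normalized = TRUE),
    class = "importance_table")
  colnames(tab$fold_importances) <- tab$gene_ids
  tally <- structure(setNames(c(2L, 2L, 2L, 1L), c("gD", "gB", "gA", "gC")),
                     class = "vote_tally", k = 2L)
  cfg <- selector_config(min_votes = 1, n_final = 3)
  sel <- select_by_votes(tally, tab, cfg)
  # gD wins on importance; gA before gB on id; gC dropped by truncation
  expect_identical(sel$gene_ids, c("gD", "gA", "gB"))
  # min_votes drops low-vote genes rather than padding
  cfg2 <- selector_config(min_votes = 2, n_final = 10)
  expect_identical(select_by_votes(tally, tab, cfg2)$gene_ids,
                   c("gD", "gA", "gB"))
  # auto resolves to ceiling(0.75 k)
  expect_equal(genevote:::resolve_min_votes("auto", 8), 6)
  expect_error(genevote:::resolve_min_votes(9, 8), "min_votes")
})

test_that("embedded SVM ranking puts the informative gene first", {
  set.seed(8)
  n <- 40
  y <- rep(0:1, each = n / 2)
  v <- cbind(y + rnorm(n, sd = 0.2), rnorm(n), rnorm(n))
  m <- tiny_matrix(v, y, gene_ids = c("gS", "gN1", "gN2"))
  gs <- embedded_svm_rank(m)
  expect_identical(gs$gene_ids[1], "gS")
  expect_length(embedded_svm_rank(m, top_m = 3), 3)
  expect_setequal(embedded_svm_rank(m, top_m = 3)$gene_ids, m$gene_ids)
  expect_error(embedded_svm_rank(tiny_matrix(v, rep(1, n))), "two classes")
})

test_that("merge_unique keeps unique genes with reproducible order", {
  a <- gene_set(c("A", "B"), c(1, 2))
  b <- gene_set(c("B", "C"), c(3, 4))
  merged <- merge_unique(list(a, b), seed = 1)
  expect_setequal(merged$gene_ids, c("A", "B", "C"))
  expect_identical(merge_unique(list(a, b), seed = 1)$gene_ids,
                   merged$gene_ids)
  # disjoint sets: all genes survive
  d <- merge_unique(list(gene_set(c("X", "Y")), gene_set("Z")), seed = 2)
  expect_setequal(d$gene_ids, c("X", "Y", "Z"))
  # idempotent on a single set (as a set)
  expect_setequal(merge_unique(list(a), seed = 3)$gene_ids, a$gene_ids)
})

test_that("correlation pruning drops later redundant genes", {
  set.seed(10)
  n <- 300
  a <- rnorm(n)
  b <- 0.75 * a + sqrt(1 - 0.75^2) * rnorm(n)  # r(A,B) ~ 0.75
  c_g <- 0.75 * b + sqrt(1 - 0.75^2) * rnorm(n) # r(B,C) ~ 0.75, r(A,C) ~ 0.56
  m <- tiny_matrix(cbind(a, b, c_g), rep(0:1, n / 2),
                   gene_ids = c("gA", "gB", "gC"))
  r_ab <- abs(cor(a, b)); r_bc <- abs(cor(b, c_g)); r_ac <- abs(cor(a, c_g))
  stopifnot(r_ab >= 0.5, r_bc >= 0.5)
  genes <- gene_set(c("gA", "gB", "gC"))
  kept <- correlation_prune(m, genes, r_max = 0.5, scope = "marginal")
  # chain: B dropped against A; C survives iff r(A,C) < 0.5
  expected <- if (r_ac < 0.5) c("gA", "gC") else "gA"
  expect_identical(kept$gene_ids, expected)

  # identical twins: exactly the earlier-ranked one kept
  m2 <- tiny_matrix(cbind(a, a), rep(0:1, n / 2), gene_ids = c("g1", "g2"))
  expect_identical(correlation_prune(m2, gene_set(c("g2", "g1")), 0.5)$gene_ids,
                   "g2")
  # independent genes unchanged
  m3 <- tiny_matrix(matrix(rnorm(n * 3), n, 3), rep(0:1, n / 2))
  expect_length(correlation_prune(m3, gene_set(m3$gene_ids), 0.5), 3)
  # constant gene treated as uncorrelated
  m4 <- tiny_matrix(cbind(a, 1), rep(0:1, n / 2), gene_ids = c("g1", "gconst"))
  expect_length(correlation_prune(m4, gene_set(m4$gene_ids), 0.5), 2)
  expect_error(correlation_prune(m4, gene_set("missing"), 0.5),
               "not present")
})

test_that("within-class pruning spares complementary markers, drops true copies", {
  ds <- generate_dataset(simulation_spec(
    n_samples = 200, n_genes = 30, n_informative = 4,
    n_redundant_per_informative = 1, redundancy_rho = 0.9,
    effect_size = 2, seed = 9))
  m <- ds$matrix
  ids <- c(ds$truth$informative_gene_ids, ds$truth$redundant_gene_ids)
  kept <- correlation_prune(m, gene_set(ids), 0.5, scope = "within-class")
  # independent markers marginally correlate ~0.5 through the label but are
  # complementary, so all four survive; the rho = 0.9 copies do not
  expect_setequal(kept$gene_ids, ds$truth$informative_gene_ids)
  # marginal scope on the same input also removes label-induced pairs
  kept_m <- correlation_prune(m, gene_set(ids), 0.5, scope = "marginal")
  expect_lt(length(kept_m), length(kept) + length(ds$truth$redundant_gene_ids))
})

test_that("pruned sets verify max pairwise |r| < r_max post hoc", {
  for (seed in 1:5) {
    ds <- generate_dataset(simulation_spec(
      n_samples = 80, n_genes = 40, n_informative = 5,
      n_redundant_per_informative = 3, redundancy_rho = 0.85, seed = seed))
    for (scope in c("marginal", "within-class")) {
      kept <- correlation_prune(ds$matrix, gene_set(ds$matrix$gene_ids), 0.5,
                                scope = scope)
      vals <- ds$matrix$values[, kept$gene_ids]
      if (scope == "within-class")
        vals <- genevote:::center_by_class(vals, ds$matrix$labels)
      cm <- abs(cor(vals))
      diag(cm) <- 0
      expect_lt(max(cm), 0.5)
    }
  }
})

test_that("threshold sweep scores grids and prefers the smallest tie", {
  ds <- sim60(3)
  folds <- make_folds(ds$matrix$labels, 4, seed = 2)
  sw <- sweep_threshold(ds$matrix, folds, stub_provider(),
                        grid = c(0.2, 0.6), config = selector_config())
  expect_equal(nrow(sw$curve), 2)
  expect_true(all(sw$curve$accuracy >= 0 & sw$curve$accuracy <= 1))
  expect_true(sw$best_t %in% c(0.2, 0.6))
  # single-point grid
  sw1 <- sweep_threshold(ds$matrix, folds, stub_provider(), grid = 0.3,
                         config = selector_config())
  expect_equal(sw1$best_t, 0.3)
  # a near-empty selection at t = 0.99 cannot beat the best threshold
  sw2 <- sweep_threshold(ds$matrix, folds, stub_provider(),
                         grid = c(0, 0.99), config = selector_config())
  acc <- setNames(sw2$curve$accuracy, sw2$curve$t)
  expect_gte(acc[["0"]], acc[["0.99"]])
  expect_error(sweep_threshold(ds$matrix, folds, stub_provider(),
                               grid = c(-0.1, 0.5)), "within")
})

test_that("select_genes output is a subset of input genes and deterministic", {
  ds <- sim60(4)
  m <- scale_minmax(ds$matrix)
  folds <- make_folds(m$labels, 4, seed = 5)
  cfg <- selector_config(threshold = 0, min_votes = "auto", n_final = 20,
                         seed = 5)
  a <- select_genes(m, folds, cfg, provider = stub_provider())
  b <- select_genes(m, folds, cfg, provider = stub_provider())
  expect_identical(a$genes$gene_ids, b$genes$gene_ids)
  expect_true(all(a$genes$gene_ids %in% m$gene_ids))
  expect_lte(length(a$genes), 20)
  expect_named(a$stage_counts,
               c("nonzero_per_fold", "above_threshold_per_fold",
                 "post_vote", "post_prune"))
  # optional stages extend, never fabricate
  cfg2 <- selector_config(threshold = 0, n_final = 20, seed = 5,
                          use_embedded_svm = TRUE, use_mrmr_union = TRUE)
  c2 <- select_genes(m, folds, cfg2, provider = stub_provider(),
                     mrmr_cfg = mrmr_config(m = 5))
  expect_true(all(c2$genes$gene_ids %in% m$gene_ids))
  expect_true(all(c("svm_redundant", "svm_unique") %in%
                    names(c2$stage_counts)))
})
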