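# Synthetic two-class expression data with planted signal and redundancy.

#' Specify a synthetic expression dataset
#'
#' Defaults emulate the small-n / large-p microarray regime the pipeline is
#' aimed at: 28 balanced samples, 1070 probe-set features, a small block of
#' informative genes carrying an additive class-mean shift, and correlated
#' redundant copies of each informative gene.
#'
#' @param n_samples number of samples.
#' @param n_genes total number of genes.
#' @param n_informative number of genes given a class-mean shift.
#' @param effect_size class-mean shift in units of the within-class SD.
#' @param n_redundant_per_informative correlated copies planted per
#'   informative gene.
#' @param redundancy_rho target Pearson correlation of each redundant copy
#'   to its parent, in \[0, 1\].
#' @param class_balance fraction of samples in class 1, in (0, 1).
#' @param noise_sd within-class standard deviation of every gene.
#' @param seed integer; the same spec (including seed) reproduces the
#'   dataset bit for bit.
#' @return object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_samples = 28, n_genes = 1070,
                            n_informative = 10, effect_size = 2,
                            n_redundant_per_informative = 3,
                            redundancy_rho = 0.8, class_balance = 0.5,
                            noise_sd = 1, seed = 0) {
  spec <- structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         n_informative = as.integer(n_informative),
         effect_size = effect_size,
         n_redundant_per_informative = as.integer(n_redundant_per_informative),
         redundancy_rho = redundancy_rho, class_balance = class_balance,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "SimulationSpec")
  n_planted <- spec$n_informative * (1L + spec$n_redundant_per_informative)
  if (spec$n_samples < 2) stopf("n_samples must be >= 2")
  if (n_planted > spec$n_genes)
    stopf("infeasible spec: %d planted genes exceed %d total genes",
          n_planted, spec$n_genes)
  if (spec$redundancy_rho < 0 || spec$redundancy_rho > 1)
    stopf("redundancy_rho must be in [0, 1]")
  if (spec$class_balance <= 0 || spec$class_balance >= 1)
    stopf("class_balance must be in (0, 1)")
  if (spec$noise_sd <= 0) stopf("noise_sd must be positive")
  spec
}

#' Generate a synthetic two-class expression dataset
#'
#' Every gene is Gaussian with SD `noise_sd` within class. Informative genes
#' add `effect_size * noise_sd` to their class-1 mean. Each redundant gene is
#' `rho * parent + sqrt(1 - rho^2) * noise`, giving correlation close to
#' `redundancy_rho` with its parent. Remaining genes are label-independent
#' noise. Planted genes are placed at seeded random positions so column
#' order carries no information.
#'
#' @param spec a [simulation_spec()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`, a list
#'   with `informative_gene_ids`, `redundant_gene_ids` and `parent_map`
#'   (named character vector: redundant id -> parent informative id).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  n <- spec$n_samples
  p <- spec$n_genes
  n_pos <- max(1L, min(n - 1L, as.integer(round(n * spec$class_balance))))
  labels <- c(rep(0L, n - n_pos), rep(1L, n_pos))
  gene_ids <- sprintf("g%0*d_at", max(4L, nchar(p)), seq_len(p))
  with_seed(spec$seed, {
    v <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    n_inf <- spec$n_informative
    n_red <- n_inf * spec$n_redundant_per_informative
    planted <- if (n_inf > 0) sample.int(p, n_inf + n_red) else integer(0)
    inf_idx <- planted[seq_len(n_inf)]
    red_idx <- planted[-seq_len(n_inf)]
    if (n_inf > 0) {
      shift <- spec$effect_size * spec$noise_sd
      v[labels == 1L, inf_idx] <- v[labels == 1L, inf_idx] + shift
    }
    parent_map <- character(0)
    if (n_red > 0) {
      parents <- rep(inf_idx, each = spec$n_redundant_per_informative)
      rho <- spec$redundancy_rho
      # the parent's marginal SD includes the between-class mean shift;
      # scaling the added noise to it makes cor(copy, parent) ~ rho exactly
      bb <- n_pos / n
      parent_sd <- sqrt(spec$noise_sd^2 +
                          (spec$effect_size * spec$noise_sd)^2 * bb * (1 - bb))
      eps <- matrix(stats::rnorm(n * n_red, sd = parent_sd), n, n_red)
      v[, red_idx] <- rho * v[, parents] + sqrt(1 - rho^2) * eps
      parent_map <- stats::setNames(gene_ids[parents], gene_ids[red_idx])
    }
  })
  m <- expression_matrix(v, gene_ids = gene_ids,
                         sample_ids = sprintf("s%03d", seq_len(n)),
                         labels = labels, positive_label = 1)
  truth <- list(informative_gene_ids = gene_ids[inf_idx],
                redundant_gene_ids = gene_ids[red_idx],
                parent_map = parent_map)
  list(matrix = m, truth = truth)
}

#' Write ground truth as two-column TSV (gene_id, role/parent)
#' @param truth the `truth` element of [generate_dataset()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  df <- rbind(
    data.frame(gene_id = truth$informative_gene_ids,
               parent = "informative", stringsAsFactors = FALSE),
    data.frame(gene_id = truth$redundant_gene_ids,
               parent = unname(truth$parent_map[truth$redundant_gene_ids]),
               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
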