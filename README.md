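# genevote

Interpretable gene selection and classification for two-class,
small-sample, high-dimensional expression data (tens of samples, a
thousand or more probe-set features). `genevote` is aimed at analysts who
need a *defensible gene list* as much as a classification number: every
stage is deterministic under explicit seeds, every selected gene can be
traced to the cross-validation folds that voted for it, and redundancy is
removed by an explicit correlation rule rather than buried inside a
model.

## The method in brief

Given a samples × genes matrix `X` and binary labels `y`:

1. **Scale** each gene to [0, 1] by min-max (fitted on training data).
2. **Partition** samples into stratified k folds (default k = 8).
3. **Per-fold importance**: fit a gradient-boosted tree ensemble on each
   fold's training side; record per-gene split-gain importances and
   max-normalise within fold.
4. **Threshold** each fold's genes (strictly above `t`); `t` is fixed or
   chosen by an accuracy sweep with the one-standard-error rule.
5. **Vote**: a gene's score is the number of folds it survived. Keep
   genes with at least `ceiling(0.75 k)` votes, rank by
   (votes, mean importance), truncate to `n_final` (default 50).
6. **Prune redundancy**: greedily drop any gene with
   `|r| >= 0.5` to an already-kept gene (within-class correlation by
   default; plain marginal Pearson available).
7. **Evaluate** by stratified k-fold CV: sensitivity `TP/(TP+FN)`,
   specificity `TN/(TN+FP)`, accuracy, and AUC by the closed form
   `(1 + TPR − FPR)/2`, reported as mean ± SD over folds.

Classic and ensemble **mRMR** (exhaustive multi-start, stratified
bootstrap; quotient or difference scheme), an embedded linear-SVM
ranking, and a seed-deterministic hyperparameter search over bounded
spaces for two boosted-tree parameter vocabularies are included. A
synthetic-data generator with planted informative genes and correlated
redundant blocks makes the whole pipeline testable without restricted
clinical data. The methods vignette
(`vignettes/genevote-methods.Rmd`) documents every design choice.

## Worked example

```r
library(genevote)

# 28 balanced samples x 1070 genes, 10 informative (effect 2 SD),
# 3 redundant copies each at rho = 0.8 -- the regime the tool targets
ds    <- generate_dataset(simulation_spec(seed = 1))
m     <- scale_minmax(ds$matrix)
folds <- make_folds(m$labels, k = 8, seed = 1)

sel <- select_genes(m, folds, selector_config(seed = 1))
sel$genes
#> gene_set of 3 genes
#>   rank  gene_id score
#> 1    1 g0978_at     8
#> 2    2 g0957_at     8
#> 3    3 g0966_at     7

cv <- cross_validate(ds$matrix, sel$genes, folds,
                     classifier = "catboost-style", seed = 1)
cv
#> 8-fold cross-validation (catboost-style)
#>   accuracy     0.97 ± 0.09
#>   sensitivity  0.94 ± 0.18
#>   specificity  1.00 ± 0.00
#>   auc          0.97 ± 0.09
```

The scores in `sel$genes` are vote counts: `g0978_at` passed the
importance threshold in all 8 folds, `g0966_at` in 7. All three survivors
are planted signal genes; their redundant copies were removed by the
correlation prune. The evaluation table reads as mean ± SD over the 8
held-out folds; the AUC is the closed form applied to each fold's
sensitivity and false-positive rate.

At larger sample sizes the recovery is near-complete: on 60 × 500
datasets with 10 planted genes the default pipeline recovers ≥ 80% of
them in 15 of 20 seeds (this is asserted by the test suite).

A full run — selection, optional tuning, evaluation of several
classifiers, correlation heat map/dendrogram, JSON/TSV artifacts — is one
call (`run_pipeline(config)`) or one shell command:

```sh
exec/genevote run --config config.yml
exec/genevote simulate --n-samples 28 --n-genes 1070 --seed 1 --out m.tsv --truth t.tsv
exec/genevote select --matrix m.tsv --k 8 --threshold sweep --out selected.tsv --report stages.json
```

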