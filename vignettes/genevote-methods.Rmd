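---
title: "Hybrid gene selection by cross-fold importance voting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid gene selection by cross-fold importance voting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-class expression studies in oncology routinely face the small-n /
large-p regime: a few dozen patient samples against a thousand or more
probe-set features. In that regime a single classifier fit is fragile, a
single feature ranking is unstable, and a gene list produced by one model
on one split of the data is hard to defend biologically. `genevote`
implements a hybrid selection-and-classification workflow built around
three stabilising ideas:

1. **Cross-fold importance voting.** A gradient-boosted tree ensemble is
   fitted once per cross-validation fold (on the training side only), its
   per-gene split-gain importances are max-normalised within each fold,
   genes above an importance threshold survive the fold, and each gene's
   *vote count* is the number of folds it survived. Genes are then ranked
   by (votes, mean importance) and truncated to a target list size.
   Consistency across resampled fits, not magnitude in a single fit, is
   the selection signal.
2. **Minimum-redundancy maximum-relevance (mRMR) ranking**, classic and in
   two ensemble forms (exhaustive multi-start and bootstrap), as an
   optional complementary path into the candidate set.
3. **Correlation-redundancy pruning**: a greedy scan that drops any gene
   whose absolute correlation with an already-kept gene reaches a cutoff
   (default 0.5), so the final list is non-redundant by construction.

A seed-deterministic hyperparameter search over bounded spaces for the two
boosted-tree parameter vocabularies, and a stratified k-fold evaluation
harness reporting sensitivity, specificity, accuracy and AUC as mean ± SD
over folds, complete the pipeline.

## The selection model, step by step

Let $X \in \mathbb{R}^{n \times p}$ be the expression matrix (samples by
genes) and $y \in \{0,1\}^n$ the class labels.

**Scaling.** Each gene is min-max scaled,
$x' = (x - \min x)/(\max x - \min x)$. Ranges are fitted on training data
and applied to held-out data without clipping; a gene constant on the
training side maps to 0. The evaluation harness fits the transform inside
each fold by default (`scale_mode = "per-fold"`) to keep held-out samples
out of the statistics; a `"global"` mode reproduces the simpler
scale-everything-first convention.

**Folds.** `make_folds()` builds stratified k-fold partitions by shuffling
within class under a seed and dealing round-robin, continuing the deal
across classes; fold sizes differ by at most one and per-fold class counts
stay within one of proportional.

**Per-fold importances.** The default provider (`gbt_provider()`) is a
boosted classification-tree ensemble (150 rounds, depth 3, learning rate
0.1, 50% column subsampling per tree); its total split gain per gene is
the importance. The low learning rate and column subsampling matter:
strongly informative genes shadow each other in a greedy tree, and without
per-tree feature subsampling a subset of them can absorb all the gain
while equally informative genes score zero. Subsampling decorrelates the
trees so every informative gene accumulates gain in most folds. Any object
with an `importance(values, labels)` function can stand in as provider;
`tstat_provider()` (absolute two-sample t statistic, nearest-centroid
classification) is a closed-form alternative used widely in the tests.

**Threshold.** Importances are max-normalised per fold so a threshold in
$[0,1]$ means the same thing in every fold and for every provider. A gene
survives a fold if its normalised importance is strictly greater than the
threshold. The threshold can be fixed, or swept (`threshold = "sweep"`,
the default) over a grid (default $0, 0.1, \ldots, 0.9$): each grid point
is scored by the provider classifier's cross-validated accuracy on the
genes that point selects, and the chosen threshold follows the
**one-standard-error rule** — the smallest threshold whose mean accuracy
is within one SE (over folds) of the best. The raw argmax (`rule = "max"`,
smallest threshold on exact ties) is also available, but on small samples
the accuracy curve is flat to within CV noise and its argmax is unstable;
1-SE is the standard conservative tie-break (as in CART pruning and
`glmnet`'s `lambda.1se`) and here "conservative" means the more inclusive
gene set. A grid point with an empty selection is scored as majority-class
accuracy.

**Voting and truncation.** `vote()` counts fold survivals;
`select_by_votes()` keeps genes with at least `min_votes` votes, sorts by
(votes desc, mean importance desc, gene id asc) and truncates to `n_final`
(default 50). `min_votes = "auto"` resolves to $\lceil 0.75k \rceil$ —
three-quarters consensus, in line with common stability-selection
practice, where selection-frequency thresholds of 0.6–0.9 are typical. A
majority rule admits noticeably more chance survivors at $n \le 60$;
unanimity starts dropping genuinely informative genes whose importance
fluctuates across folds.

**Optional stages.** Per-fold linear-SVM rankings (genes ordered by
absolute hyperplane weight) can be merged in by union, as can the heads of
an exhaustive mRMR ensemble; both are off by default and sit behind flags,
because their interaction with the voting path is a design choice rather
than something the workflow fixes. Merging shuffles the concatenation
under a seed before deduplicating, so merge order is reproducible but
carries no per-set precedence.

**Pruning.** `correlation_prune()` scans the ranked list and drops any
gene correlating at $|r| \ge$ `r_max` (default 0.5) with an already-kept
gene. The default correlation **scope is within-class**: each gene is
centred on its class means before correlating. The reason is a
degeneracy worth spelling out: two *conditionally independent* genes that
both carry a class-mean shift of $e$ within-class SDs are marginally
correlated at $e^2 b(1-b) / (1 + e^2 b(1-b))$ (class-1 fraction $b$) —
exactly 0.5 at $e = 2$, $b = 0.5$. Plain marginal pruning at 0.5 then
removes most of a panel of strong, mutually complementary markers, which
is the opposite of what redundancy pruning is for. Centring on class
means measures the correlation that remains *beyond* the label — the
same reason coexpression analyses remove group effects before building
networks. The literal marginal rule is kept as `scope = "marginal"`. An
optional second pass at `r_max + 0.01` is available and off by default.

## mRMR

Relevance is $|r(x_j, y)|$ (point-biserial; an ANOVA F option exists) and
redundancy is the mean $|r|$ to the already-selected set. The greedy step
maximises either the quotient `rel / max(red, epsilon)` (default,
`epsilon = 1e-6` guarding near-zero denominators) or the difference
`rel - red`; both schemes necessarily agree on the first gene. Ties break
by gene id, which keeps the selection invariant under column
permutations. The exhaustive ensemble forces the i-th solution to start
from the i-th most relevant gene; the bootstrap ensemble re-ranks
class-stratified bootstrap resamples. The test suite checks the full
greedy trace against an independently coded brute-force evaluation of the
criterion on dozens of random instances.

## Hyperparameter search

`builtin_space()` returns the bounded spaces for the two boosted-tree
vocabularies. The two learning-rate ranges are exponents: $[-3, -0.7]$ in
base 10 (rates 0.001 to 0.2) for the catboost-style space and
$[\ln 0.001, \ln 0.3]$ for the xgboost-style space — the only readings
that produce valid learning rates. The published table these spaces
derive from prints the two parameter columns under each other's header
(iterations/rsm/l2_leaf_reg/bagging_temperature belong to one library's
vocabulary, n_estimators/gamma/colsample_bytree to the other); the
package assigns each space by parameter-name compatibility.
`m_child_weight` is normalised to `min_child_weight`. Both vocabularies
execute on the same boosted-tree backend through a documented mapping
(iterations→nrounds, depth→max_depth, rsm→colsample_bylevel,
l2_leaf_reg→lambda); `random_strength` and `bagging_temperature` have no
backend analogue and are accepted but inert.

`tune()` minimises a loss (by convention 1 − mean CV accuracy) with a
fixed trial budget (default 30, the study's stated iteration count).
`"random"` draws uniformly; `"adaptive-sequential"` spends a third of the
budget on uniform warm-up, then perturbs the incumbent best in unit-cube
coordinates with a shrinking Gaussian kernel, keeping a 20% exploration
rate. Both are exactly reproducible under the seed; a failing objective
records loss 1.0 with a warning rather than aborting the search. The
adaptive backend is compared against random on a convex toy objective in
the tests (logged, not hard-asserted, as a 20-seed median).

## Evaluation

Per fold, hard predictions give confusion counts; sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy, and AUC by the closed
form $(1 + TPR - FPR)/2$ — the area under the two-segment ROC curve
through a hard classifier's single operating point. This is deliberately
the formula-based AUC, not a score-ranking AUC (one is available behind
`score_auc = TRUE` for comparison). Summaries are mean ± SD over folds,
printed at two decimals with half-away-from-zero rounding (base R's
round-half-even cannot reproduce conventionally rounded tables:
0.905 must print as 0.91). Because mean-of-fold-AUCs and
formula-on-mean-rates differ slightly, `metrics.json` reports both. When
a rate's denominator is 0 (possible in small folds) the rate is reported
as 0 with a loud warning, keeping summaries finite.

The classification report mirrors the familiar per-class
precision/recall/F1/support table with macro (unweighted) and weighted
(support-weighted) averages, computed from pooled out-of-fold
predictions.

For leakage-free estimates of the *whole pipeline's* generalisation,
`cross_validate()` accepts a `selector` function that is re-run inside
every training fold (`make_nested_selector()`); with an empty selection
the fold falls back to majority-class prediction. The default pipeline
path — select once on all data, then cross-validate the selected genes —
follows the original workflow and is optimistic for exactly this reason;
the permuted-label calibration in the test suite uses the nested path.

## The synthetic generator

Real cohorts of this kind are rarely redistributable, so the package
ships `generate_dataset()`, whose defaults emulate the regime the
workflow targets: 28 balanced samples, 1070 probe-set-style gene ids, 10
informative genes with a class-mean shift of 2 within-class SDs, three
redundant copies per informative gene at target correlation 0.8, and
label-independent Gaussian noise elsewhere. Redundant copies are
$\rho \cdot \text{parent} + \sqrt{1-\rho^2}\,\sigma_P\,\varepsilon$ with
$\sigma_P$ the parent's marginal SD (which includes the between-class
shift), so the realised copy–parent correlation matches $\rho$. Planted
genes sit at seeded random columns; identical specs reproduce datasets
bit for bit.

What the generator does *not* emulate: batch effects, probe saturation,
missing values, heavy-tailed or heteroscedastic noise, and correlation
structure among noise genes. Passing recovery tests on this generator
therefore shows that the pipeline finds mean-shift signal and removes
planted redundancy at the stated n and p — not that it is robust to
microarray artefacts.

## Problem sizes and numerical choices

The property suites run at sizes a laptop handles comfortably: planted-
gene recovery uses 20 datasets of 60 × 500 with 10 informative genes at
effect 2.0; null calibration permutes labels on 20 datasets of 28 × 1070
and cross-validates with fully nested selection; mRMR oracle equivalence
uses 50 random instances of up to 10 genes. Determinism is asserted
byte-for-byte on repeated pipeline runs at 28 × 1070.

Other numerical conventions: strict `>` at the importance threshold;
argmax ties broken by ascending gene id everywhere; quotient denominators
floored at `epsilon`; constant genes scale to 0, correlate as 0 and are
never fabricated into any stage's output (every stage returns a subset of
its input genes); all stochastic steps (fold shuffles, merge shuffles,
bootstrap resamples, search proposals, the boosting backend) run under
explicit integer seeds with the caller's RNG state restored.

## Known limitations

- The closed-form AUC is coarser than a score-based AUC and equals it
  only for the one-threshold classifier it describes.
- Voting calibration (`min_votes`, the sweep grid) was chosen for the
  two-class balanced regime; heavily unbalanced cohorts will need
  `class_balance`-aware thresholds and possibly `scale_pos_weight`.
- The embedded-SVM and mRMR union stages are provided as flagged options;
  where they enter the flow is a documented design choice, not a claim
  about the original workflow's exact stage order.
- Multi-class problems, mutual-information mRMR estimators, and
  missing-value handling are out of scope.
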