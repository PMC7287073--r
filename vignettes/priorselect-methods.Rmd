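---
title: "Methods: prior-knowledge and data-driven feature selection for drug sensitivity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prior-knowledge and data-driven feature selection for drug sensitivity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The modeling problem

Large cell-line screens measure, for each drug and each cancer cell line,
the area under the dose-response curve (AUC in [0, 1]; lower = stronger
effect), together with multi-omic descriptions of the lines: continuous
log-scale gene expression, binary per-gene mutation calls, binary
copy-number calls on genomic segments, and a tissue of origin. With tens of
thousands of molecular features but only hundreds of screened lines per
drug, per-drug regression is badly under-determined, and the central
question this package addresses is *how to choose the feature set*: does
prior biological knowledge about a drug (its targets, its target pathway,
curated expression signatures) buy as much predictive power as the full
genome-wide feature set, or as automatic data-driven selection?

Seven strategies are compared per drug:

* **OT** — expression, mutation and CNV features of the drug's direct
  target genes, plus a full one-hot tissue encoding. A CNV segment
  qualifies when it covers at least one target gene.
* **PG** — the same extraction over the union of all pathway gene sets
  that contain at least one target, united with the targets themselves.
* **OT+S / PG+S** — OT or PG extended with per-sample activity scores of
  coherent expression signatures.
* **GW** — all expression features, no tissue encoding (the baseline).
* **GW_SEL_EN / GW_SEL_RF** — GW pruned by stability selection (feeding an
  elastic net) or by random-forest importance (feeding a random forest).

Models are elastic net and random forest regressors. The protocol, applied
independently per drug and strategy: randomly hold out 30% of samples as a
test set, tune hyperparameters by 3-fold cross-validation on the training
part (MSE criterion), refit, predict the test set; repeat 5 times with
fresh splits and average the metrics.

## Evaluation

Raw test RMSE is incomparable across drugs because response distributions
differ: a drug with almost-constant AUC yields a tiny RMSE for a useless
model. Every model is therefore referred to a *dummy* predictor that always
outputs the training-set mean response:

$$\mathrm{RelRMSE} = \frac{\mathrm{RMSE}_{dummy}}{\mathrm{RMSE}_{model}},$$

so 1 means "no better than predicting the mean" and values above 1 mean
actual learning. Drugs whose *best* strategy fails to clear
$1 + \varepsilon$ are excluded from comparative analyses; the cutoff
$\varepsilon$ defaults to 0.01 and is configuration-exposed, since "close
to baseline" is inherently a judgment call, and the excluded count is
always reported so users can judge it. Pearson correlation between
predictions and observed AUC (two-sided p from the Student-t
transformation on $n-2$ degrees of freedom) is the cross-drug comparison
metric; the best strategy per drug is the correlation argmax, with ties
resolved toward fewer features and then lexical strategy name, so sparser
models win disputes they do not lose outright.

Pathway-level comparisons split strategies into a genome-wide group (GW,
GW_SEL_*) and a biologically driven group (OT, PG, OT+S, PG+S); per drug
each group is represented by its best mean correlation, and per target
pathway the two sets of per-drug values are compared by a one-sided
Mann-Whitney-Wilcoxon test. The test direction follows the larger group
median within each pathway — we report which group is favored alongside
the p-value rather than fixing a global alternative.

## Signature scores

A signature is a named gene set expected to move coherently. For a
signature with expression submatrix $X$ (genes × samples), the coherence
score is the mean Pearson correlation over all unordered gene pairs across
samples. Its definition is sometimes phrased over the columns of
$X^{i\times n}$ while being interpreted as gene-gene correlation; we
compute gene-gene correlations (rows of $X$, i.e. profiles across samples),
which matches the interpretation and the coherence-score literature, and
expose the sample-axis reading as a non-default option
(`coherence_score(X, axis = "samples")`). Signatures with CS below 0.1 are
discarded by default. Activity of a retained signature in a sample is the
mean of its genes' expression z-scores, with z-scoring statistics computed
over *all* samples by default (`scope = "global"`), reproducing the
convention of scoring signatures on the whole resource before any
train/test split. This is a deliberate, documented exception to the
no-leakage rule — the transform sees test samples' expression, though never
any response value — and `scope = "train_only"` is available where strict
transform hygiene matters more than comparability.

Zero-variance and absent signature genes are dropped (with warnings or
logged counts) rather than failing the signature, which keeps small
fixtures and sparsely covered signatures usable; a signature loses its
score only when fewer than two usable genes remain.

## Data-driven selection

*Stability selection* fits lasso regressions on `n_subsamples = 100`
random half-samples (drawn without replacement — the classical subsampling
construction; with-replacement bootstrap is an option) over a 30-value
log-spaced penalty grid taken from the full-data lasso path. A feature's
score is the maximum over the grid of its nonzero-coefficient frequency;
ranking ties break by mean absolute coefficient, then feature id.
*Forest-importance selection* ranks by impurity-decrease importance
(normalized to sum to 1) from a 500-tree regression forest; permutation
importance was considered and not used, as impurity decrease is what a
forest provides directly.

The number of features kept, *k*, is not thresholded on frequency but
chosen per drug by inner cross-validation: for each candidate k the
downstream model family is scored by CV MSE on the top-k features, and the
smallest k among minimizers wins. This mirrors reporting a per-drug optimal
k rather than a universal cutoff. Selection always runs inside each
repetition's training partition — a leakage probe in the test suite
corrupts held-out responses and asserts that selection, standardization and
the fitted model are bit-identical.

## Model fitting choices

Elastic net: continuous features are z-scored with training statistics
(applied unchanged to the test matrix); binary features (mutation, CNV,
tissue one-hots) stay 0/1 so their coefficients read as group effects.
The mixing parameter grid is {0.1, …, 1.0} with a 30-value penalty path
per mixing value (both configurable); effects are absolute coefficients on
the standardized scale. Random forest: 500 trees (fixed), depth in
{unlimited, 10, 20} and features-per-split in {√p, p/3, p} tuned by CV.
A single-feature design falls back to ordinary least squares, since a
penalty path over one coefficient is vacuous. Constant columns are dropped
with a warning; a constant response is an error, not a silent fit.

Tissue encoding keeps all levels rather than dropping a reference level:
the encoding is meant to be readable as per-tissue effects and penalized
models handle the redundancy. Sample restriction for biologically driven
strategies requires only the modalities that actually contribute a column
for that drug — a drug with no CNV feature does not lose CNV-unmeasured
cell lines. This per-strategy restriction is why genome-wide models
systematically see more samples than target-restricted ones.

## The synthetic generator

`generate_dataset()` emulates the structure of the screen so every stage
is testable end to end: expression with per-gene means uniform on
log2-intensity-like values 4–10 and unit residual scale; signature genes
sharing a latent factor with pairwise correlation `signature_rho`; mutation
prevalences uniform on [0.01, 0.2] over a gene subset sized ~2% of the
gene universe; CNV segments covering contiguous gene blocks (so the
segment-covers-a-target rule is exercised with hits and misses); 13
tissues; and per-drug AUC

$$\mathrm{AUC} = \mathrm{clip}\!\left(\mathrm{base} - \textstyle\sum_j w_j\, d_j + \varepsilon,\; 0, 1\right),$$

where drivers $d_j$ are standardized planted features and
$\varepsilon \sim N(0, \sigma^2)$. Drivers *subtract* because lower AUC
means stronger efficacy. Mechanisms: `target_expression` (one target gene's
expression), `target_mutation` (one target's mutation call), `polygenic`
(40 genes with weights $w = \text{effect}/\sqrt{40}$), and `null` (pure
noise). Targets are drawn from planted pathways, so PG construction finds
them. The `narrow` regime makes the driver act only in the
`outlier_fraction` most extreme lines, emulating drugs with a small
over-expressing sensitive subpopulation. Defaults — 500 cell lines, 2,000
genes, effect size 0.3 AUC units, noise SD 0.05, baseline AUC 0.85 —
reflect screen-like proportions (hundreds of lines, responses concentrated
near high AUC, signal clearly above noise for targeted drugs) at a scale
where a full run takes minutes.

What the generator does **not** emulate: realistic expression marginal
shapes (latent factors are Gaussian), linkage between mutation and
expression of the same gene, dose-response curve fitting (AUC is generated
directly), inter-drug correlation, or batch structure. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
recovers planted signal under fair conditions — not that any particular
biological conclusion transfers to a real screen.

## Determinism and numerics

All randomness flows from one integer seed; per-component substreams are
derived as `(seed * 7919 + offset * 104729) mod (2^31 - 19)` so stages can
be re-run independently yet reproducibly, and two pipeline runs with one
seed write byte-identical result tables. RelRMSE returns an infinite
sentinel (with a warning) for an exact model and errors on the 0/0 case of
a constant test response perfectly matched by the dummy. Correlation is
undefined (error) below 3 samples or at zero variance. CV fold assignments
are drawn once per fit from the substream, so elastic-net mixing values
compete on identical folds.

## Problem sizes in the shipped tests

The test suite validates the heavy claims at reduced but honest scale,
chosen so the full suite runs in minutes on one CPU: strategy-ranking
recovery on one 500 × 2,000 bundle (effect 0.3, noise 0.05); biomarker
recovery over 20 generator seeds at 300 × 500; exclusion calibration on 10
noise + 10 signal drugs at n = 500; stability-selection support recovery
over 50 seeds at n = 300 with 2 true predictors among 200 decoys; and
statistical machinery against permutation and exhaustive-enumeration
oracles. Elastic-net grids in these runs use a reduced mixing grid — grid
density affects runtime, not the claims under test — while generator
parameters are held at the defaults above.

## Known limitations

* Ineligibility (no targets, or no feature beyond tissue) silently removes
  drugs from biologically driven strategies; comparisons across strategy
  groups are therefore over the eligible intersection, as in the source
  analyses.
* Averaging p-values over repetitions (as done for the reported tables) is
  a summary, not a combined test; significance statements should use the
  per-repetition records.
* The Mann-Whitney pathway test treats per-drug best correlations as
  exchangeable units; drugs sharing targets violate independence mildly.
* `scope = "global"` signature scoring leaks expression (not response)
  information across the split, by design and documented above.
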