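# priorselect

Per-drug prediction of cancer cell-line drug sensitivity from multi-omic
features, built to answer a feature-selection question: for a given
compound, does prior biological knowledge — its target genes, its target
pathway, curated gene-expression signatures — predict the dose-response
AUC as well as the full genome-wide expression matrix or automatic
data-driven feature selection?

The package is aimed at computational biologists analyzing cell-line
screens (or benchmarking selection strategies on simulated ones). It
implements:

* **Feature-set strategies** per drug: only-targets (**OT**: target
  expression/mutation/CNV + tissue one-hot), pathway genes (**PG**: the
  union of pathway gene sets hit by the targets, plus the targets),
  signature-extended variants (**OT+S**, **PG+S**), genome-wide expression
  (**GW**), and genome-wide with automatic selection (**GW_SEL_EN**:
  stability selection → elastic net; **GW_SEL_RF**: forest importance →
  random forest).
* **Signature scoring**: the coherence score of a signature *S* with
  expression matrix *X* (genes × samples) is the mean pairwise Pearson
  correlation among its genes; signatures with CS(*S*) ≥ 0.1 (default)
  become per-sample activity features, the mean of per-gene expression
  z-scores.
* **Models and protocol**: elastic net and random forest, tuned by 3-fold
  CV (MSE) on a 70% training split, evaluated on the held-out 30%,
  repeated 5 times and averaged.
* **Evaluation**: Pearson correlation with the test response, and the
  relative RMSE against a training-mean dummy baseline,

  ```
  RelRMSE = RMSE_dummy / RMSE_model
  ```

  with baseline value 1; drugs whose best model stays at the baseline are
  excluded from comparative analyses. Reports include the best strategy
  per drug, one-sided Mann-Whitney-Wilcoxon comparisons of genome-wide vs
  biologically driven strategies per target pathway, and feature-type
  frequencies among top-ranked features.
* **A synthetic screen generator** with planted mechanisms
  (target-expression-driven, target-mutation-driven, polygenic, null), so
  the whole pipeline — including driver recovery — is testable without any
  external downloads.

## Worked example

Simulate a screen, pick a drug whose sensitivity is driven by expression of
its target, and compare the only-targets strategy against genome-wide:

```r
library(priorselect)

cfg <- synthetic_config(n_cell_lines = 300, n_genes = 800, n_drugs = 6,
                        n_pathways = 10, n_signatures = 8,
                        signature_size_range = c(5, 12), seed = 42)
bundle <- generate_dataset(cfg)

mech <- vapply(bundle$ground_truth, `[[`, "", "mechanism")
drug <- bundle$annotations[[ names(mech)[mech == "target_expression"][1] ]]

protocol <- experiment_protocol(seed = 7, en_alpha_grid = c(0.5, 1))
ot <- run_drug(drug, "OT", bundle$data, bundle$responses, protocol)
gw <- run_drug(drug, "GW", bundle$data, bundle$responses, protocol)
aggregate_records(rbind(ot$records, gw$records))
```

```
  drug_id strategy n_samples n_features rel_rmse pearson_r
1    D002    GW_EN       300        800     2.46     0.926
2    D002    OT_EN       300         14     2.61     0.928
```

Both models clearly beat the dummy baseline (RelRMSE ≈ 2.5 ≫ 1), and the
14-feature only-targets model matches the 800-feature genome-wide model's
test correlation (0.928 vs 0.926). The fitted effects also recover the
planted biomarker — the largest mean elastic-net effect is
`expression:G00502`, exactly the generator's driver for this drug:

```r
sort(Reduce(`+`, lapply(ot$fits, `[[`, "feature_effects")), decreasing = TRUE)[1:3]
# expression:G00502, tissue:tissue01, tissue:tissue02
bundle$ground_truth[[drug$drug_id]]$drivers
#         type  source weight
#   expression  G00502    0.3
```

`run_all()` (or `Rscript scripts/priorselect run-all --config cfg.yaml`)
chains every stage — simulation or data loading, signature scoring,
feature construction, modeling, reporting — for all drugs and strategies
and writes the aggregated tables, exclusions, best-model list, pathway
tests and feature-type frequencies to an output directory, reproducibly
from a single seed.

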