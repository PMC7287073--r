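# Hand-built dataset with fully known structure, used by the feature
# construction tests: 12 cell lines, 6 genes, 3 mutation genes, 2 CNV
# segments, 5 tissues. Gene A sits in segment SEG1 (with B, C); gene F is
# covered by no segment.
toy_dataset <- function() {
  cells <- sprintf("c%02d", 1:12)
  genes <- c("A", "B", "C", "D", "E", "F")
  set.seed(42)
  expr <- matrix(rnorm(12 * 6, 7), 12, 6, dimnames = list(cells, genes))
  mut <- matrix(rbinom(12 * 3, 1, 0.3), 12, 3,
                dimnames = list(cells, c("A", "D", "F")))
  cnv <- matrix(rbinom(12 * 2, 1, 0.3), 12, 2,
                dimnames = list(cells, c("SEG1", "SEG2")))
  tissues <- sprintf("t%d", 1:5)
  tissue <- setNames(rep(tissues, length.out = 12), cells)
  omics_dataset(expr, mut, cnv,
                segment_genes = list(SEG1 = c("A", "B", "C"), SEG2 = c("D", "E")),
                tissue = tissue, tissue_levels = tissues)
}

toy_responses <- function(drug_id = "drugX", cells = sprintf("c%02d", 1:12),
                          auc = NULL) {
  set.seed(43)
  response_table(data.frame(drug_id = drug_id, cell_line = cells,
                            auc = auc %||% runif(length(cells), 0.6, 0.95)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A signature_scores object built by hand (no coherence filtering), for
# structural tests of add_signatures().
fake_scores <- function(samples, n_sig, prefix = "SIG") {
  nms <- sprintf("%s%03d", prefix, seq_len(n_sig))
  act <- matrix(rnorm(length(samples) * n_sig), length(samples), n_sig,
                dimnames = list(samples, nms))
  structure(list(cs = setNames(rep(1, n_sig), nms), retained = nms,
                 activity = act, threshold = 0.1),
            class = "signature_scores")
}

small_bundle <- function(seed = 11, n = 120, genes = 300, drugs = 8, ...) {
  generate_dataset(synthetic_config(n_cell_lines = n, n_genes = genes,
                                    n_drugs = drugs, n_pathways = 8,
                                    n_signatures = 6,
                                    signature_size_range = c(5, 10),
                                    seed = seed, ...))
}

# Independent coherence oracle: the O(i^2) double loop over unordered
# gene pairs.
brute_force_cs <- function(X) {
  i <- nrow(X)
  total <- 0; npairs <- 0
  for (a in seq_len(i - 1)) for (b in (a + 1):i) {
    total <- total + cor(X[a, ], X[b, ])
    npairs <- npairs + 1
  }
  total / npairs
}

# A ready-ranked selection_result (uniform scores), for choose_k tests.
selection_result_for_test <- function(ids) {
  structure(list(ranked_features = ids,
                 scores = setNames(rep(1, length(ids)), ids),
                 k = NA_integer_, method = "stability", details = list()),
            class = "selection_result")
}

drugs_with_mechanism <- function(bundle, mechanism) {
  ids <- names(bundle$ground_truth)[vapply(bundle$ground_truth, `[[`, "",
                                           "mechanism") == mechanism]
  bundle$annotations[ids]
}
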