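test_that("OT assembles exactly the target-derived columns plus full tissue one-hot", {
  d <- toy_dataset()
  resp <- toy_responses()
  # target A: in expression, in mutation, covered by SEG1 -> 1+1+1+5 columns
  drug <- drug_annotation("drugX", "A", "pw")
  fm <- build_ot(drug, d, resp)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(ncol(fm$values), 8)
  expect_equal(as.vector(table(fm$feature_meta$type)[c("expression", "mutation",
                                                       "cnv", "tissue")]),
               c(1L, 1L, 1L, 5L))
  expect_equal(fm$feature_meta$source[fm$feature_meta$type == "cnv"], "SEG1")
  # tissue one-hot keeps all levels and rows sum to 1
  tis <- fm$values[, fm$feature_meta$type == "tissue"]
  expect_equal(unname(rowSums(tis)), rep(1, nrow(tis)))
})

test_that("drugs with no usable target feature are ineligible, not errors", {
  d <- toy_dataset()
  resp <- toy_responses()
  expect_true(is_ineligible(build_ot(drug_annotation("d0", character(0), "pw"),
                                     d, resp)))
  # a target absent from every modality leaves only tissue -> ineligible
  expect_true(is_ineligible(build_ot(drug_annotation("drugX", "NOPE", "pw"),
                                     d, resp)))
  # gene E: not in expression? it is; pick a gene only in a segment map:
  # target B is in expression and SEG1 -> eligible with 1 expr + 1 cnv
  fm <- build_ot(drug_annotation("drugX", "B", "pw"), d, resp)
  expect_equal(sum(fm$feature_meta$type != "tissue"), 2)
})

test_that("PG universe is the union of hit pathways plus the targets themselves", {
  d <- toy_dataset()
  resp <- toy_responses()
  pw <- gene_set_collection(list(P1 = c("A", "B"), P2 = c("C")), "pathway")
  fm <- build_pg(drug_annotation("drugX", "A", "pw"), d, pw, resp)
  expr_src <- fm$feature_meta$source[fm$feature_meta$type == "expression"]
  expect_setequal(expr_src, c("A", "B"))
  fm2 <- build_pg(drug_annotation("drugX", c("A", "C"), "pw"), d, pw, resp)
  expect_setequal(fm2$feature_meta$source[fm2$feature_meta$type == "expression"],
                  c("A", "B", "C"))
  # a target in no pathway still enters the universe
  fm3 <- build_pg(drug_annotation("drugX", "F", "pw"), d, pw, resp)
  expect_setequal(fm3$feature_meta$source[fm3$feature_meta$type == "expression"],
                  "F")
})

test_that("PG universe size follows set arithmetic on overlapping pathways", {
  set.seed(30)
  genes <- sprintf("G%03d", 1:200)
  p1 <- sample(genes, 10)
  shared <- sample(p1, 5)
  p2 <- c(shared, sample(setdiff(genes, p1), 15))  # |P2| = 20, overlap 5
  p3 <- sample(setdiff(genes, c(p1, p2)), 30)
  pw <- gene_set_collection(list(P1 = p1, P2 = p2, P3 = p3), "pathway")
  targets <- c(p1[1], shared[1])   # hits P1 and P2, not P3
  expr <- matrix(rnorm(20 * 200), 20, 200,
                 dimnames = list(sprintf("c%02d", 1:20), genes))
  d <- omics_dataset(expr, tissue = setNames(rep("t1", 20), rownames(expr)),
                     tissue_levels = "t1")
  resp <- toy_responses("dX", rownames(expr))
  fm <- build_pg(drug_annotation("dX", targets, "pw"), d, pw, resp)
  expr_src <- fm$feature_meta$source[fm$feature_meta$type == "expression"]
  expect_length(expr_src, 10 + 20 - 5)   # targets already inside the union
  expect_setequal(expr_src, union(p1, p2))
})

test_that("OT features are a subset of PG features for every synthetic drug", {
  b <- small_bundle(seed = 19)
  for (drug in b$annotations) {
    ot <- build_ot(drug, b$data, b$responses)
    pg <- build_pg(drug, b$data, b$pathways, b$responses)
    if (is_ineligible(ot) || is_ineligible(pg)) next
    expect_true(all(colnames(ot$values) %in% colnames(pg$values)))
  }
})

test_that("GW keeps masked-modality cell lines that OT must drop", {
  d <- toy_dataset()
  # mask mutation for half the lines; target A uses mutation, so OT loses them
  d2 <- omics_dataset(d$expression, d$mutation[1:6, ], d$cnv, d$segment_genes,
                      d$tissue, d$tissue_levels)
  resp <- toy_responses()
  drug <- drug_annotation("drugX", "A", "pw")
  ot <- build_ot(drug, d2, resp)
  gw <- build_gw(drug, d2, resp)
  expect_equal(nrow(gw$values), 12)
  expect_equal(nrow(ot$values), 6)
  expect_true("c07" %in% gw$sample_ids && !("c07" %in% ot$sample_ids))
  expect_equal(ncol(gw$values), 6)   # all expression genes, no tissue columns
  expect_true(all(gw$feature_meta$type == "expression"))
})

test_that("drugs whose targets need no masked modality keep those samples", {
  d <- toy_dataset()
  # B has no mutation column; masking mutation rows must not shrink OT(B)
  d2 <- omics_dataset(d$expression, d$mutation[1:6, ], d$cnv, d$segment_genes,
                      d$tissue, d$tissue_levels)
  fm <- build_ot(drug_annotation("drugX", "B", "pw"), d2, toy_responses())
  expect_equal(nrow(fm$values), 12)
})

test_that("signature columns append after base columns, in collection order", {
  d <- toy_dataset()
  resp <- toy_responses()
  base <- build_ot(drug_annotation("drugX", "A", "pw"), d, resp)
  sc <- fake_scores(d$cell_lines, 128)
  fm <- add_signatures(base, sc)
  expect_equal(ncol(fm$values), 8 + 128)   # 136-column OT+S layout
  expect_equal(fm$feature_meta$type[9:136], rep("signature", 128))
  expect_equal(fm$feature_meta$source[9:136], sc$retained)
  expect_equal(colnames(fm$values)[1:8], colnames(base$values))
})

test_that("add_signatures handles empty retention, missing samples, duplicates", {
  d <- toy_dataset()
  base <- build_ot(drug_annotation("drugX", "A", "pw"), d, toy_responses())
  none <- fake_scores(d$cell_lines, 3)
  none$retained <- character(0)
  none$activity <- none$activity[, 0, drop = FALSE]
  expect_identical(add_signatures(base, none), base)
  short <- fake_scores(d$cell_lines[1:5], 3)
  expect_error(add_signatures(base, short), "c06")
  dup <- fake_scores(d$cell_lines, 2)
  colnames(dup$activity) <- dup$retained <- c("SIG001", "SIG001")
  expect_error(add_signatures(base, dup))
})

test_that("a drug with no responded cell line yields an empty, flagged GW matrix", {
  d <- toy_dataset()
  resp <- toy_responses("other_drug")
  expect_warning(fm <- build_gw(drug_annotation("drugX", "A", "pw"), d, resp),
                 "no responded")
  expect_equal(nrow(fm$values), 0)
})

test_that("feature matrices reject duplicated (type, source) pairs", {
  v <- matrix(rnorm(4), 2, 2, dimnames = list(c("a", "b"), NULL))
  meta <- data.frame(type = c("expression", "expression"), source = c("g", "g"))
  expect_error(feature_matrix(v, meta), "duplicate")
})

test_that("rebuilding from identical inputs gives identical column order", {
  b <- small_bundle(seed = 23)
  drug <- b$annotations[[1]]
  f1 <- build_pg(drug, b$data, b$pathways, b$responses)
  f2 <- build_pg(drug, b$data, b$pathways, b$responses)
  expect_identical(f1, f2)
})

test_that("strategy specs expose capability flags", {
  expect_true(strategy_spec("OT+S")$uses_signatures)
  expect_false(strategy_spec("GW")$uses_targets)
  expect_equal(strategy_spec("GW_SEL_EN")$selection, "stability")
  expect_equal(strategy_spec("GW")$modalities, "expression")
  expect_error(strategy_spec("bogus"))
})
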