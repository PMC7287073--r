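STRATEGIES <- c("OT", "PG", "OT+S", "PG+S", "GW", "GW_SEL_EN", "GW_SEL_RF")

#' Strategy descriptor
#'
#' The feature-set strategies compared by the pipeline: only-targets (OT),
#' pathway genes (PG), each optionally extended with signature scores
#' (OT+S, PG+S), genome-wide expression (GW), and genome-wide expression
#' with automatic selection (GW_SEL_EN: stability selection feeding elastic
#' net; GW_SEL_RF: forest-importance selection feeding random forest).
#'
#' @param name One of `"OT"`, `"PG"`, `"OT+S"`, `"PG+S"`, `"GW"`,
#'   `"GW_SEL_EN"`, `"GW_SEL_RF"`.
#' @return A `strategy_spec` list with capability flags and the omics
#'   modalities the strategy draws on.
#' @export
strategy_spec <- function(name) {
  name <- match.arg(name, STRATEGIES)
  gw <- name %in% c("GW", "GW_SEL_EN", "GW_SEL_RF")
  structure(list(
    name = name,
    uses_targets = !gw,
    uses_pathways = name %in% c("PG", "PG+S"),
    uses_signatures = name %in% c("OT+S", "PG+S"),
    selection = switch(name, GW_SEL_EN = "stability",
                       GW_SEL_RF = "forest_importance", "none"),
    modalities = if (gw) "expression"
                 else c("expression", "mutation", "cnv", "tissue")),
    class = "strategy_spec")
}

#' Construct a feature matrix
#'
#' The per-drug design matrix: a numeric samples x features matrix plus
#' per-column metadata tagging every feature with its type (`expression`,
#' `mutation`, `cnv`, `tissue`, `signature`) and source (gene id, segment
#' id, tissue label, or signature name).
#'
#' @param values Numeric matrix, rows = cell lines.
#' @param feature_meta Data frame with columns `type` and `source`, one row
#'   per column of `values`; (type, source) pairs must be unique.
#' @export
feature_matrix <- function(values, feature_meta) {
  stopifnot(is.matrix(values), is.data.frame(feature_meta),
            all(c("type", "source") %in% colnames(feature_meta)),
            nrow(feature_meta) == ncol(values),
            nrow(values) == 0L || !is.null(rownames(values)))
  stopifnot(all(feature_meta$type %in%
                  c("expression", "mutation", "cnv", "tissue", "signature")))
  key <- paste(feature_meta$type, feature_meta$source, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (type, source) feature: ", key[duplicated(key)][1L])
  colnames(values) <- key
  structure(list(values = values, feature_meta = feature_meta,
                 sample_ids = rownames(values) %||% character(0)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$feature_meta$type)
  cat(sprintf("<feature_matrix> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

ineligible <- function(drug_id, reason) {
  structure(list(drug_id = drug_id, reason = reason), class = "drug_ineligible")
}

#' @export
print.drug_ineligible <- function(x, ...) {
  cat(sprintf("<drug_ineligible> %s: %s\n", x$drug_id, x$reason))
  invisible(x)
}

#' Test for an ineligibility marker
#' @param x Object returned by a feature builder.
#' @export
is_ineligible <- function(x) inherits(x, "drug_ineligible")

# Shared biologically-driven extraction: given a gene universe, pull
# expression and mutation columns for universe genes, CNV columns for
# segments covering >=1 universe gene, plus a full one-hot tissue encoding.
# Samples are cell lines with a response for the drug and with every
# modality that actually contributes a column; a drug with no non-tissue
# column is ineligible.
extract_bio_features <- function(drug, universe, data, responses) {
  resp_cells <- responses$cell_line[responses$drug_id == drug$drug_id]
  expr_genes <- intersect(colnames(data$expression), universe)
  mut_genes <- if (is.null(data$mutation)) character(0) else
    intersect(colnames(data$mutation), universe)
  segs <- if (is.null(data$cnv)) character(0) else
    names(data$segment_genes)[vapply(data$segment_genes, function(g)
      length(intersect(g, universe)) > 0, logical(1))]
  segs <- intersect(colnames(data$cnv), segs)
  if (length(expr_genes) + length(mut_genes) + length(segs) == 0L)
    return(ineligible(drug$drug_id,
                      "no target-derived feature beyond tissue type"))
  av <- data$availability
  need <- av$expression
  if (length(mut_genes)) need <- need & av$mutation
  if (length(segs)) need <- need & av$cnv
  if (!is.null(data$tissue)) need <- need & av$tissue
  samples <- intersect(av$cell_line[need], resp_cells)
  blocks <- list()
  meta <- list()
  if (length(expr_genes)) {
    blocks$expr <- data$expression[samples, expr_genes, drop = FALSE]
    meta$expr <- data.frame(type = "expression", source = expr_genes,
                            stringsAsFactors = FALSE)
  }
  if (length(mut_genes)) {
    blocks$mut <- data$mutation[samples, mut_genes, drop = FALSE]
    meta$mut <- data.frame(type = "mutation", source = mut_genes,
                           stringsAsFactors = FALSE)
  }
  if (length(segs)) {
    blocks$cnv <- data$cnv[samples, segs, drop = FALSE]
    meta$cnv <- data.frame(type = "cnv", source = segs, stringsAsFactors = FALSE)
  }
  if (!is.null(data$tissue)) {
    lv <- data$tissue_levels
    onehot <- vapply(lv, function(l) as.numeric(data$tissue[samples] == l),
                     numeric(length(samples)))
    onehot <- matrix(onehot, nrow = length(samples),
                     dimnames = list(samples, lv))
    blocks$tissue <- onehot
    meta$tissue <- data.frame(type = "tissue", source = lv,
                              stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- samples
  feature_matrix(values, do.call(rbind, c(meta, list(make.row.names = FALSE))))
}

#' Only-targets (OT) feature set
#'
#' Features restricted to the drug's direct targets: each target gene's
#' expression and mutation call where measured, CNV calls of every segment
#' covering at least one target gene, plus one binary column per tissue
#' level. Drugs with no annotated target, or whose targets yield no feature
#' beyond tissue type, are ineligible (a typed marker, not an error).
#'
#' @param drug A [drug_annotation()].
#' @param data An [omics_dataset()].
#' @param responses A [response_table()]; samples are restricted to cell
#'   lines screened for this drug.
#' @return A [feature_matrix()], or a `drug_ineligible` marker.
#' @export
build_ot <- function(drug, data, responses) {
  if (!length(drug$targets))
    return(ineligible(drug$drug_id, "no annotated targets"))
  extract_bio_features(drug, drug$targets, data, responses)
}

#' Pathway-genes (PG) feature set
#'
#' The gene universe is the union of all members of every pathway containing
#' at least one of the drug's targets, united with the targets themselves;
#' feature extraction then proceeds as in [build_ot()] over this universe.
#'
#' @inheritParams build_ot
#' @param pathways A [gene_set_collection()] of pathways.
#' @export
build_pg <- function(drug, data, pathways, responses) {
  if (!length(drug$targets))
    return(ineligible(drug$drug_id, "no annotated targets"))
  hit <- vapply(pathways$sets, function(g)
    length(intersect(g, drug$targets)) > 0, logical(1))
  universe <- union(unlist(pathways$sets[hit], use.names = FALSE), drug$targets)
  extract_bio_features(drug, universe, data, responses)
}

#' Append signature-score features (OT+S / PG+S)
#'
#' Adds one activity column per retained signature to a biologically driven
#' base matrix. Base columns keep their order; signatures follow in
#' collection order.
#'
#' @param base A [feature_matrix()] from [build_ot()] or [build_pg()].
#' @param scores A `signature_scores` object whose activity matrix covers at
#'   least the base samples.
#' @export
add_signatures <- function(base, scores) {
  if (is_ineligible(base)) return(base)
  stopifnot(inherits(base, "feature_matrix"),
            inherits(scores, "signature_scores"))
  if (!length(scores$retained)) return(base)
  missing <- setdiff(base$sample_ids, rownames(scores$activity))
  if (length(missing))
    stop("no signature activity for sample(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  act <- scores$activity[base$sample_ids, , drop = FALSE]
  meta <- rbind(base$feature_meta,
                data.frame(type = "signature", source = colnames(act),
                           stringsAsFactors = FALSE))
  feature_matrix(cbind(base$values, act), meta)
}

#' Genome-wide (GW) feature set
#'
#' All expression features, no tissue encoding; samples are every cell line
#' with expression data and a response for the drug — no mutation or CNV
#' requirement, so genome-wide models typically see more samples than
#' target-restricted ones.
#'
#' @inheritParams build_ot
#' @export
build_gw <- function(drug, data, responses) {
  resp_cells <- responses$cell_line[responses$drug_id == drug$drug_id]
  samples <- intersect(data$cell_lines, resp_cells)
  if (!length(samples))
    warning(sprintf("drug %s has no responded cell line with expression",
                    drug$drug_id))
  feature_matrix(data$expression[samples, , drop = FALSE],
                 data.frame(type = "expression",
                            source = colnames(data$expression),
                            stringsAsFactors = FALSE))
}

#' Build the feature matrix for any strategy
#'
#' Dispatcher over [build_ot()], [build_pg()], [add_signatures()] and
#' [build_gw()] (the GW_SEL strategies reuse the GW matrix; their selection
#' happens at model-fitting time on training data only).
#'
#' @inheritParams build_pg
#' @param strategy Strategy name or [strategy_spec()].
#' @param scores `signature_scores`, required for the +S strategies.
#' @export
build_features <- function(strategy, drug, data, responses, pathways = NULL,
                           scores = NULL) {
  spec <- if (inherits(strategy, "strategy_spec")) strategy else strategy_spec(strategy)
  base <- switch(spec$name,
    "OT" = , "OT+S" = build_ot(drug, data, responses),
    "PG" = , "PG+S" = build_pg(drug, data,
                               pathways %||% stop("PG strategies need pathways"),
                               responses),
    build_gw(drug, data, responses))
  if (spec$uses_signatures)
    base <- add_signatures(base, scores %||% stop("+S strategies need signature scores"))
  base
}
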