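#' Read a labeled numeric matrix from TSV
#'
#' Matrices are exchanged as UTF-8 TSV with a header row of feature ids and a
#' first column of cell-line ids (the GDSC-style tabular layout). Binary
#' matrices (mutation calls, CNV calls) are validated to contain only 0/1.
#'
#' @param path Path to the TSV file.
#' @param value_kind `"continuous"` or `"binary"`. Binary matrices must
#'   contain only 0 and 1.
#' @return A numeric matrix with cell lines as rownames and features as
#'   colnames.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, value_kind = c("continuous", "binary")) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop_format("malformed matrix header in '%s': need id column plus >=1 feature", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        bad <- which(is.na(vn))[1L]
        stop_format("non-numeric value in '%s' at row '%s', column '%s'",
                    path, ids[bad], colnames(vals)[j])
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (value_kind == "binary") {
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(m))
      stop_format("binary matrix '%s' has value %s at row '%s', column '%s'",
                  path, format(m[bad[1L]]), rownames(m)[rc[1L]], colnames(m)[rc[2L]])
    }
  }
  m
}

#' Write a labeled numeric matrix to TSV
#'
#' Inverse of [read_matrix()]; round-trips labels and values exactly (values
#' are written with full precision).
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name for the leading id column.
#' @export
write_matrix <- function(m, path, id_column = "cell_line") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated. The
#' description field is discarded; duplicate genes within a set are dropped
#' keeping the first occurrence.
#'
#' @param path Path to a GMT file.
#' @param kind `"pathway"` or `"signature"`; recorded on the collection.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `kind`.
#' @export
read_gmt <- function(path, kind = c("pathway", "signature")) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_format("GMT line %d has %d fields; need name, description, >=1 gene",
                  i, length(fields))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) next
    sets[[fields[1L]]] <- genes
  }
  if (anyDuplicated(names(sets)))
    stop_format("duplicate set names in '%s'", path)
  gene_set_collection(sets, kind)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param kind `"pathway"` or `"signature"`.
#' @export
gene_set_collection <- function(sets, kind = c("pathway", "signature")) {
  kind <- match.arg(kind)
  stopifnot(is.list(sets))
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
    if (any(!lengths(sets))) stop("empty gene sets are not allowed")
  }
  structure(list(sets = sets, kind = kind), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d %s sets (sizes %s)\n",
              length(x$sets), x$kind,
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Construct a per-drug annotation
#'
#' Holds the drug's known target genes (merged from up to two sources) and
#' its target-pathway class label (one of the screening resource's mechanism
#' classes). A drug may have no targets, in which case only genome-wide
#' strategies apply to it.
#'
#' @param drug_id Drug identifier.
#' @param targets Character vector of target gene ids (may be empty).
#' @param target_pathway Non-empty pathway class label.
#' @param target_sources Subset of `c("gdsc", "drugbank")`.
#' @export
drug_annotation <- function(drug_id, targets, target_pathway,
                            target_sources = "gdsc") {
  stopifnot(is.character(drug_id), length(drug_id) == 1L,
            nzchar(target_pathway))
  targets <- sort(unique(as.character(targets)))
  targets <- targets[nzchar(targets)]
  stopifnot(all(target_sources %in% c("gdsc", "drugbank")))
  structure(list(drug_id = drug_id, targets = targets,
                 target_pathway = as.character(target_pathway),
                 target_sources = sort(unique(target_sources))),
            class = "drug_annotation")
}

#' Read drug annotations, merging targets from two sources
#'
#' The primary file (screening-resource annotations) defines the drug
#' universe and the target-pathway class. The optional secondary file
#' (DrugBank-style) contributes extra targets for drugs it matches; its
#' targets are unioned with the primary ones. Secondary-only drugs are
#' skipped with a warning. Both files are TSV with columns
#' `drug_id`, `targets` (semicolon-separated, possibly empty) and, for the
#' primary file, `target_pathway`.
#'
#' @param path_gdsc Primary annotation TSV.
#' @param path_drugbank Optional secondary annotation TSV, or `NULL`.
#' @return Named list of [drug_annotation()] objects, keyed by drug id.
#' @export
read_drug_annotations <- function(path_gdsc, path_drugbank = NULL) {
  parse_targets <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  }
  gdsc <- utils::read.delim(path_gdsc, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE, quote = "",
                            colClasses = "character")
  need <- c("drug_id", "targets", "target_pathway")
  if (!all(need %in% colnames(gdsc)))
    stop_format("primary annotation file '%s' must have columns %s",
                path_gdsc, paste(need, collapse = ", "))
  db <- NULL
  if (!is.null(path_drugbank)) {
    db <- utils::read.delim(path_drugbank, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE, quote = "",
                            colClasses = "character")
    orphan <- setdiff(db$drug_id, gdsc$drug_id)
    if (length(orphan)) {
      warning(sprintf("skipping %d drug(s) present only in the secondary file: %s",
                      length(orphan), paste(orphan, collapse = ", ")))
      db <- db[db$drug_id %in% gdsc$drug_id, , drop = FALSE]
    }
  }
  out <- lapply(seq_len(nrow(gdsc)), function(i) {
    id <- gdsc$drug_id[i]
    targets <- parse_targets(gdsc$targets[i])
    sources <- "gdsc"
    if (!is.null(db) && id %in% db$drug_id) {
      extra <- parse_targets(db$targets[db$drug_id == id][1L])
      if (length(extra)) {
        targets <- union(targets, extra)
        sources <- c("gdsc", "drugbank")
      }
    }
    drug_annotation(id, targets, gdsc$target_pathway[i], sources)
  })
  names(out) <- gdsc$drug_id
  out
}

#' Write drug annotations
#'
#' @param annotations Named list of [drug_annotation()] objects.
#' @param path Output TSV.
#' @export
write_drug_annotations <- function(annotations, path) {
  df <- data.frame(
    drug_id = vapply(annotations, `[[`, "", "drug_id"),
    targets = vapply(annotations, function(a) paste(a$targets, collapse = ";"), ""),
    target_pathway = vapply(annotations, `[[`, "", "target_pathway"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a long-format drug response table
#'
#' Columns `drug_id`, `cell_line`, `auc`; at most one record per
#' (drug, cell line); AUC (area under the dose-response curve) must lie in
#' \[0, 1\], lower values meaning stronger drug effect.
#'
#' @param path TSV path.
#' @return A `data.frame` of class `response_table`.
#' @export
read_response_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  response_table(df)
}

#' @rdname read_response_table
#' @param df Data frame with columns `drug_id`, `cell_line`, `auc`.
#' @export
response_table <- function(df) {
  need <- c("drug_id", "cell_line", "auc")
  if (!all(need %in% colnames(df)))
    stop_format("response table needs columns %s", paste(need, collapse = ", "))
  df <- df[, need]
  df$auc <- as.numeric(df$auc)
  if (any(df$auc < 0 | df$auc > 1, na.rm = TRUE))
    stop_format("AUC values outside [0, 1]")
  if (anyDuplicated(df[, c("drug_id", "cell_line")]))
    stop_format("duplicate (drug, cell line) records in response table")
  class(df) <- c("response_table", "data.frame")
  df
}

#' @rdname read_response_table
#' @param responses A `response_table`.
#' @export
write_response_table <- function(responses, path) {
  utils::write.table(as.data.frame(responses), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble an aligned multi-omic cell-line dataset
#'
#' Bundles continuous expression, binary mutation calls, binary CNV segment
#' calls with a segment-to-gene map, and a tissue label per cell line.
#' Modalities are aligned to the union of cell lines; which modalities are
#' actually measured for a given line is recorded in the `availability`
#' mask rather than imputed. Row (cell-line) order follows the expression
#' matrix and is never silently reordered.
#'
#' @param expression Continuous matrix, cell lines x genes (log-scale units).
#' @param mutation Binary matrix, cell lines x genes; rows may be a subset of
#'   the expression cell lines.
#' @param cnv Binary matrix, cell lines x segments.
#' @param segment_genes Named list mapping each CNV segment to the gene ids
#'   it covers (possibly empty).
#' @param tissue Named character vector: tissue label per cell line.
#' @param tissue_levels Declared tissue vocabulary; defaults to the sorted
#'   unique labels.
#' @return An `omics_dataset` with elements `expression`, `mutation`, `cnv`,
#'   `segment_genes`, `tissue`, `tissue_levels`, `cell_lines`, `availability`.
#' @export
omics_dataset <- function(expression, mutation = NULL, cnv = NULL,
                          segment_genes = NULL, tissue = NULL,
                          tissue_levels = NULL) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  cells <- rownames(expression)
  check_binary <- function(m, what) {
    if (is.null(m)) return(NULL)
    stopifnot(is.matrix(m), !is.null(rownames(m)))
    if (!is_binary01(m)) stop_format("%s matrix must be binary 0/1", what)
    extra <- setdiff(rownames(m), cells)
    if (length(extra))
      stop_format("%s matrix has cell lines absent from expression: %s",
                  what, paste(utils::head(extra, 3), collapse = ", "))
    m
  }
  mutation <- check_binary(mutation, "mutation")
  cnv <- check_binary(cnv, "cnv")
  if (!is.null(cnv)) {
    segment_genes <- segment_genes %||% stop("cnv matrix requires segment_genes")
    missing_seg <- setdiff(colnames(cnv), names(segment_genes))
    if (length(missing_seg))
      stop_format("segments missing from segment_genes map: %s",
                  paste(utils::head(missing_seg, 3), collapse = ", "))
  }
  if (!is.null(tissue)) {
    stopifnot(!is.null(names(tissue)))
    tissue <- tissue[cells[cells %in% names(tissue)]]
    tissue_levels <- tissue_levels %||% sort(unique(unname(tissue)))
    bad <- setdiff(unique(tissue), tissue_levels)
    if (length(bad))
      stop_format("tissue labels outside declared vocabulary: %s",
                  paste(bad, collapse = ", "))
  }
  availability <- data.frame(
    cell_line = cells,
    expression = TRUE,
    mutation = if (is.null(mutation)) FALSE else cells %in% rownames(mutation),
    cnv = if (is.null(cnv)) FALSE else cells %in% rownames(cnv),
    tissue = if (is.null(tissue)) FALSE else cells %in% names(tissue),
    stringsAsFactors = FALSE)
  structure(list(expression = expression, mutation = mutation, cnv = cnv,
                 segment_genes = segment_genes, tissue = tissue,
                 tissue_levels = tissue_levels, cell_lines = cells,
                 availability = availability),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf(paste0("<omics_dataset> %d cell lines | %d expression genes | ",
                     "%s mutation genes | %s CNV segments | %s tissues\n"),
              length(x$cell_lines), ncol(x$expression),
              if (is.null(x$mutation)) 0 else ncol(x$mutation),
              if (is.null(x$cnv)) 0 else ncol(x$cnv),
              length(x$tissue_levels %||% character(0))))
  invisible(x)
}
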