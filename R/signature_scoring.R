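#' Coherence score of a gene signature
#'
#' The coherence score (CS) of a signature is the mean pairwise Pearson
#' correlation among its genes across samples: values near 1 (or -1)
#' indicate that the signature's genes move together (or in strict
#' opposition), values near 0 an incoherent gene set. Signatures are
#' admitted as features only when sufficiently coherent (see
#' [filter_signatures()], default threshold 0.1).
#'
#' @param X Numeric matrix of the signature's genes: genes x samples
#'   (>= 2 genes). Genes with zero variance across samples contribute no
#'   valid pairs and are excluded with a warning.
#' @param axis `"genes"` (default): correlate gene profiles across samples.
#'   `"samples"`: correlate sample profiles across genes, an alternative
#'   reading of the definition, exposed for comparison.
#' @return Mean Pearson correlation over all unordered pairs, in \[-1, 1\].
#' @export
coherence_score <- function(X, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(X))
  M <- if (axis == "genes") t(X) else X   # columns become the correlated units
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance unit(s) from coherence score",
                    sum(sds == 0)))
    M <- M[, sds > 0, drop = FALSE]
  }
  k <- ncol(M)
  if (k < 2L) stop("coherence score undefined: fewer than 2 units with variance")
  C <- stats::cor(M)
  (sum(C) - k) / (k * (k - 1))
}

#' Per-sample signature activity scores
#'
#' Activity of a signature in a sample is the mean of its genes' expression
#' z-scores: each gene is z-scored across the scope samples, then z-scores
#' are averaged over the signature's genes present in the matrix. Genes
#' absent from the matrix are dropped (count reported via message); genes
#' with zero variance within scope are dropped; signatures with no usable
#' gene are excluded with a warning.
#'
#' @param expression Matrix samples x genes.
#' @param sets A [gene_set_collection()] of signatures.
#' @param scope `"global"` (z-score over all samples, the whole-resource
#'   convention) or `"train_only"` (z-scoring statistics from
#'   `train_samples` only, avoiding transform leakage into held-out data).
#' @param train_samples Required for `scope = "train_only"`: sample ids used
#'   to compute means/sds.
#' @return Matrix samples x signatures of activity scores.
#' @export
signature_activity <- function(expression, sets,
                               scope = c("global", "train_only"),
                               train_samples = NULL) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(expression), inherits(sets, "gene_set_collection"))
  if (scope == "train_only") {
    if (is.null(train_samples)) stop("train_only scope requires train_samples")
    ref <- expression[train_samples, , drop = FALSE]
  } else ref <- expression
  mu <- colMeans(ref)
  sds <- apply(ref, 2L, stats::sd)
  dropped_absent <- 0L
  cols <- list()
  for (nm in names(sets$sets)) {
    genes <- sets$sets[[nm]]
    present <- intersect(genes, colnames(expression))
    dropped_absent <- dropped_absent + length(genes) - length(present)
    present <- present[sds[present] > 0]
    if (!length(present)) {
      warning(sprintf("signature '%s' has no usable genes; excluded", nm))
      next
    }
    z <- sweep(sweep(expression[, present, drop = FALSE], 2L, mu[present], `-`),
               2L, sds[present], `/`)
    cols[[nm]] <- rowMeans(z)
  }
  if (dropped_absent > 0L)
    message(sprintf("signature_activity: %d signature gene(s) absent from the expression matrix were dropped",
                    dropped_absent))
  if (!length(cols))
    return(matrix(numeric(0), nrow = nrow(expression), ncol = 0,
                  dimnames = list(rownames(expression), NULL)))
  do.call(cbind, cols)
}

#' Score and filter a signature collection
#'
#' Computes the coherence score of every signature on the expression matrix,
#' retains those at or above the threshold, and returns their activity
#' scores. Signatures with fewer than two usable genes get CS = NA and are
#' never retained.
#'
#' @inheritParams signature_activity
#' @param threshold Minimum coherence score for retention (default 0.1).
#' @return A `signature_scores` list: `cs` (named vector), `retained`
#'   (character), `activity` (samples x retained signatures), `threshold`.
#' @export
score_signatures <- function(expression, sets, threshold = 0.1,
                             scope = c("global", "train_only"),
                             train_samples = NULL) {
  scope <- match.arg(scope)
  cs <- vapply(names(sets$sets), function(nm) {
    present <- intersect(sets$sets[[nm]], colnames(expression))
    if (length(present) < 2L) return(NA_real_)
    tryCatch(coherence_score(t(expression[, present, drop = FALSE])),
             error = function(e) NA_real_)
  }, numeric(1))
  activity <- signature_activity(expression, sets, scope, train_samples)
  scores <- structure(list(cs = cs, retained = colnames(activity) %||% character(0),
                           activity = activity, activity_all = activity,
                           threshold = NA_real_),
                      class = "signature_scores")
  filter_signatures(scores, threshold)
}

#' @rdname score_signatures
#' @param scores A `signature_scores` object with `cs` computed.
#' @export
filter_signatures <- function(scores, threshold = 0.1) {
  stopifnot(inherits(scores, "signature_scores"))
  pool <- scores$activity_all %||% scores$activity
  keep <- names(scores$cs)[!is.na(scores$cs) & scores$cs >= threshold]
  keep <- intersect(colnames(pool), keep)
  scores$retained <- keep
  scores$activity <- pool[, keep, drop = FALSE]
  scores$threshold <- threshold
  scores
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("<signature_scores> %d/%d signatures retained at CS >= %s\n",
              length(x$retained), length(x$cs), format(x$threshold)))
  invisible(x)
}
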