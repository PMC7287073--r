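#' Configuration for the synthetic multi-omic generator
#'
#' The generator emulates the structure of a large cell-line drug screen at
#' reduced scale: a continuous log-scale expression matrix with
#' block-correlated signature genes, sparse binary mutation calls, binary
#' CNV calls on contiguous gene segments, tissue labels, drug annotations
#' whose targets come from planted pathways, and dose-response AUC generated
#' under known mechanisms. Lower AUC means stronger drug effect, so planted
#' drivers *subtract* from the baseline response.
#'
#' Default counts keep the real screen's rough proportions (mutation and CNV
#' features each about 2% of the expression feature count, 13 tissues) at a
#' scale where a full pipeline run takes minutes.
#'
#' @param n_cell_lines,n_genes Dataset dimensions.
#' @param n_pathways,pathway_size_range Planted pathway collection.
#' @param n_signatures,signature_size_range,signature_rho Signature gene
#'   blocks; `signature_rho` is the pairwise correlation of genes within a
#'   signature (shared latent factor).
#' @param n_tissues Number of tissue-of-origin labels.
#' @param n_drugs Number of simulated compounds (>= 1).
#' @param mechanism_mix Named proportions over
#'   `target_expression`, `target_mutation`, `polygenic`, `null`; must sum
#'   to 1.
#' @param effect_size Response shift per unit of standardized driver, AUC
#'   units.
#' @param noise_sd Residual AUC noise standard deviation.
#' @param base_auc Baseline mean AUC (screens concentrate near high AUC).
#' @param regime `"wide"`: drivers act across the whole population;
#'   `"narrow"`: a driver acts only in the `outlier_fraction` of lines with
#'   the most extreme driver feature (the over-expressed-target pattern seen
#'   for kinase inhibitors with a small sensitive subpopulation).
#' @param outlier_fraction Fraction of sensitive lines in the narrow regime.
#' @param missing_mutation_rate,missing_cnv_rate Fractions of cell lines
#'   with the modality unmeasured (masked, not imputed).
#' @param n_mutation_genes,n_cnv_segments,segment_size_range Optional
#'   overrides for the sparse modalities; defaults scale with `n_genes`.
#' @param seed Single integer seed; all per-component substreams derive
#'   from it deterministically.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cell_lines = 500, n_genes = 2000,
                             n_pathways = 25, pathway_size_range = c(10, 60),
                             n_signatures = 20, signature_size_range = c(5, 20),
                             signature_rho = 0.5, n_tissues = 13,
                             n_drugs = 20,
                             mechanism_mix = c(target_expression = 0.3,
                                               target_mutation = 0.2,
                                               polygenic = 0.2, null = 0.3),
                             effect_size = 0.3, noise_sd = 0.05,
                             base_auc = 0.85, regime = c("wide", "narrow"),
                             outlier_fraction = 0.1,
                             missing_mutation_rate = 0.1,
                             missing_cnv_rate = 0.15,
                             n_mutation_genes = NULL, n_cnv_segments = NULL,
                             segment_size_range = c(3, 8), seed = 1L) {
  regime <- match.arg(regime)
  mechanisms <- c("target_expression", "target_mutation", "polygenic", "null")
  mechanism_mix <- unlist(mechanism_mix)   # tolerate YAML-style named lists
  mix <- mechanism_mix[mechanisms]
  mix[is.na(mix)] <- 0
  names(mix) <- mechanisms
  if (abs(sum(mix) - 1) > 1e-8) stop("mechanism_mix proportions must sum to 1")
  cfg <- list(
    n_cell_lines = as.integer(n_cell_lines), n_genes = as.integer(n_genes),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_signatures = as.integer(n_signatures),
    signature_size_range = as.integer(signature_size_range),
    signature_rho = signature_rho, n_tissues = as.integer(n_tissues),
    n_drugs = as.integer(n_drugs), mechanism_mix = mix,
    effect_size = effect_size, noise_sd = noise_sd, base_auc = base_auc,
    regime = regime, outlier_fraction = outlier_fraction,
    missing_mutation_rate = missing_mutation_rate,
    missing_cnv_rate = missing_cnv_rate,
    n_mutation_genes = as.integer(n_mutation_genes %||%
                                    max(10L, round(n_genes * 310 / 17737))),
    n_cnv_segments = as.integer(n_cnv_segments %||%
                                  max(10L, round(n_genes * 425 / 17737))),
    segment_size_range = as.integer(segment_size_range),
    seed = as.integer(seed))
  with(cfg, {
    if (n_cell_lines < 10 || n_genes < 10 || n_drugs < 1 || n_tissues < 1 ||
        n_pathways < 1)
      stop("all counts must be positive (>=10 cell lines and genes, >=1 drug)")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (max(pathway_size_range) > n_genes || max(signature_size_range) > n_genes)
      stop("pathway/signature sizes exceed n_genes")
    if (n_signatures * max(signature_size_range) > n_genes)
      stop("signatures would exhaust the gene universe; reduce count or size")
    if (outlier_fraction <= 0 || outlier_fraction >= 1)
      stop("outlier_fraction must be in (0, 1)")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic screen with planted response mechanisms
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_bundle`: list with `data` (an [omics_dataset()]),
#'   `pathways` and `signatures` ([gene_set_collection()]), `annotations`
#'   (list of [drug_annotation()]), `responses` (a [response_table()]),
#'   `ground_truth` (per drug: mechanism, driver features, weights) and the
#'   `config`. Identical configs yield identical bundles.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  cells <- sprintf("CL%04d", seq_len(cfg$n_cell_lines))
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))

  # -- signatures: disjoint gene blocks sharing a latent factor -------------
  set.seed(substream_seed(cfg$seed, 1))
  sig_sizes <- sample(seq(cfg$signature_size_range[1], cfg$signature_size_range[2]),
                      cfg$n_signatures, replace = TRUE)
  sig_pool <- sample(genes, sum(sig_sizes))
  sig_sets <- split(sig_pool, rep(seq_len(cfg$n_signatures), sig_sizes))
  names(sig_sets) <- sprintf("SIG%03d", seq_len(cfg$n_signatures))
  signatures <- gene_set_collection(sig_sets, "signature")

  # -- expression: gene means on a log2-intensity-like scale ----------------
  set.seed(substream_seed(cfg$seed, 2))
  mu <- stats::runif(cfg$n_genes, 4, 10)
  names(mu) <- genes
  expr <- matrix(stats::rnorm(cfg$n_cell_lines * cfg$n_genes), nrow = cfg$n_cell_lines,
                 dimnames = list(cells, genes))
  rho <- cfg$signature_rho
  for (s in seq_along(sig_sets)) {
    f <- stats::rnorm(cfg$n_cell_lines)
    g <- sig_sets[[s]]
    expr[, g] <- sqrt(rho) * f + sqrt(1 - rho) * expr[, g, drop = FALSE]
  }
  expr <- sweep(expr, 2L, mu, `+`)

  # -- mutation calls -------------------------------------------------------
  set.seed(substream_seed(cfg$seed, 3))
  mut_genes <- sort(sample(genes, cfg$n_mutation_genes))
  prevalence <- stats::runif(cfg$n_mutation_genes, 0.01, 0.2)
  mut <- matrix(stats::rbinom(cfg$n_cell_lines * cfg$n_mutation_genes, 1L,
                              rep(prevalence, each = cfg$n_cell_lines)),
                nrow = cfg$n_cell_lines, dimnames = list(cells, mut_genes))

  # -- CNV: contiguous gene segments ---------------------------------------
  set.seed(substream_seed(cfg$seed, 4))
  seg_len <- sample(seq(cfg$segment_size_range[1], cfg$segment_size_range[2]),
                    cfg$n_cnv_segments, replace = TRUE)
  seg_start <- sample(cfg$n_genes - max(seg_len), cfg$n_cnv_segments, replace = TRUE)
  segment_genes <- lapply(seq_len(cfg$n_cnv_segments), function(i)
    genes[seq(seg_start[i], length.out = seg_len[i])])
  names(segment_genes) <- sprintf("SEG%03d", seq_len(cfg$n_cnv_segments))
  cnv_rate <- stats::runif(cfg$n_cnv_segments, 0.01, 0.2)
  cnv <- matrix(stats::rbinom(cfg$n_cell_lines * cfg$n_cnv_segments, 1L,
                              rep(cnv_rate, each = cfg$n_cell_lines)),
                nrow = cfg$n_cell_lines,
                dimnames = list(cells, names(segment_genes)))

  # -- tissue labels --------------------------------------------------------
  set.seed(substream_seed(cfg$seed, 5))
  tissue_levels <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  tissue_probs <- stats::runif(cfg$n_tissues, 0.5, 1.5)
  tissue <- sample(tissue_levels, cfg$n_cell_lines, replace = TRUE,
                   prob = tissue_probs / sum(tissue_probs))
  names(tissue) <- cells

  # -- pathways (targets are drawn from these) ------------------------------
  set.seed(substream_seed(cfg$seed, 6))
  pw_sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                     cfg$n_pathways, replace = TRUE)
  pw_sets <- lapply(pw_sizes, function(k) sample(genes, k))
  names(pw_sets) <- sprintf("PW%03d", seq_len(cfg$n_pathways))

  # -- drugs: mechanisms, targets, planted drivers --------------------------
  set.seed(substream_seed(cfg$seed, 7))
  mech_counts <- round(cfg$mechanism_mix * cfg$n_drugs)
  while (sum(mech_counts) > cfg$n_drugs)
    mech_counts[which.max(mech_counts)] <- mech_counts[which.max(mech_counts)] - 1L
  while (sum(mech_counts) < cfg$n_drugs)
    mech_counts[which.max(cfg$mechanism_mix)] <- mech_counts[which.max(cfg$mechanism_mix)] + 1L
  mechanisms <- sample(rep(names(mech_counts), mech_counts))
  drug_ids <- sprintf("D%03d", seq_len(cfg$n_drugs))

  annotations <- vector("list", cfg$n_drugs)
  ground_truth <- vector("list", cfg$n_drugs)
  auc_list <- vector("list", cfg$n_drugs)
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  for (d in seq_len(cfg$n_drugs)) {
    mech <- mechanisms[d]
    pw <- sample(cfg$n_pathways, 1L)
    if (mech == "target_mutation") {
      hits <- intersect(pw_sets[[pw]], mut_genes)
      if (!length(hits)) {   # plant a mutated gene into the chosen pathway
        planted <- sample(mut_genes, 1L)
        pw_sets[[pw]] <- c(pw_sets[[pw]], planted)
        hits <- planted
      }
      targets <- sample(hits, min(length(hits), sample(1:2, 1L)))
    } else {
      targets <- sample(pw_sets[[pw]], sample(1:3, 1L))
    }
    signal <- rep(0, cfg$n_cell_lines)
    drivers <- data.frame(type = character(0), source = character(0),
                          weight = numeric(0), stringsAsFactors = FALSE)
    if (mech == "target_expression") {
      g <- targets[1L]
      raw <- expr[, g]
      dvec <- if (cfg$regime == "narrow") {
        ind <- as.numeric(raw >= stats::quantile(raw, 1 - cfg$outlier_fraction))
        ind - mean(ind)
      } else std(raw)
      signal <- cfg$effect_size * dvec
      drivers <- data.frame(type = "expression", source = g,
                            weight = cfg$effect_size, stringsAsFactors = FALSE)
    } else if (mech == "target_mutation") {
      g <- targets[1L]
      signal <- cfg$effect_size * std(mut[, g])
      drivers <- data.frame(type = "mutation", source = g,
                            weight = cfg$effect_size, stringsAsFactors = FALSE)
    } else if (mech == "polygenic") {
      m <- min(40L, cfg$n_genes)
      gs <- sample(genes, m)
      w <- rep(cfg$effect_size / sqrt(m), m)
      signal <- as.numeric(scale(expr[, gs, drop = FALSE]) %*% w)
      drivers <- data.frame(type = "expression", source = gs, weight = w,
                            stringsAsFactors = FALSE)
    }
    eps <- stats::rnorm(cfg$n_cell_lines, 0, cfg$noise_sd)
    auc <- pmin(1, pmax(0, cfg$base_auc - signal + eps))
    annotations[[d]] <- drug_annotation(drug_ids[d], targets,
                                        names(pw_sets)[pw])
    ground_truth[[d]] <- list(drug_id = drug_ids[d], mechanism = mech,
                              drivers = drivers)
    auc_list[[d]] <- data.frame(drug_id = drug_ids[d], cell_line = cells,
                                auc = auc, stringsAsFactors = FALSE)
  }
  names(annotations) <- drug_ids
  names(ground_truth) <- drug_ids
  pathways <- gene_set_collection(pw_sets, "pathway")

  # -- modality masks: drop unmeasured rows, availability records them ------
  set.seed(substream_seed(cfg$seed, 8))
  keep_mut <- stats::runif(cfg$n_cell_lines) >= cfg$missing_mutation_rate
  keep_cnv <- stats::runif(cfg$n_cell_lines) >= cfg$missing_cnv_rate
  data <- omics_dataset(expression = expr,
                        mutation = mut[keep_mut, , drop = FALSE],
                        cnv = cnv[keep_cnv, , drop = FALSE],
                        segment_genes = segment_genes,
                        tissue = tissue, tissue_levels = tissue_levels)
  structure(list(data = data, pathways = pathways, signatures = signatures,
                 annotations = annotations,
                 responses = response_table(do.call(rbind, auc_list)),
                 ground_truth = ground_truth, config = cfg),
            class = "synthetic_bundle")
}

#' Write / read a generated bundle in the package's exchange formats
#'
#' `write_dataset()` writes every component as TSV/GMT plus a JSON manifest
#' recording the config, seed and ground truth, so a bundle regenerated from
#' the manifest is identical. `read_dataset()` reads the directory back.
#'
#' @param bundle A `synthetic_bundle` from [generate_dataset()].
#' @param out_dir Output directory.
#' @param overwrite Refuse to write into a non-empty directory unless TRUE.
#' @return `write_dataset()`: the manifest (invisibly); `read_dataset()`:
#'   a bundle-shaped list (without ground truth unless a manifest is found).
#' @export
write_dataset <- function(bundle, out_dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop(sprintf("directory '%s' is not empty; use overwrite = TRUE", out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_matrix(bundle$data$expression, p("expression.tsv"))
  write_matrix(bundle$data$mutation, p("mutation.tsv"))
  write_matrix(bundle$data$cnv, p("cnv.tsv"))
  seg <- data.frame(segment = names(bundle$data$segment_genes),
                    genes = vapply(bundle$data$segment_genes, paste,
                                   "", collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(seg, p("segment_genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tis <- data.frame(cell_line = names(bundle$data$tissue),
                    tissue = unname(bundle$data$tissue), stringsAsFactors = FALSE)
  utils::write.table(tis, p("tissue.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(bundle$pathways, p("pathways.gmt"))
  write_gmt(bundle$signatures, p("signatures.gmt"))
  write_drug_annotations(bundle$annotations, p("drugs.tsv"))
  write_response_table(bundle$responses, p("response.tsv"))
  manifest <- list(config = unclass(bundle$config),
                   seed = bundle$config$seed,
                   tissue_levels = bundle$data$tissue_levels,
                   ground_truth = bundle$ground_truth)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param dir Directory written by [write_dataset()].
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  seg_df <- utils::read.delim(p("segment_genes.tsv"), stringsAsFactors = FALSE,
                              colClasses = "character")
  segment_genes <- lapply(seg_df$genes, function(s)
    if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1L]] else character(0))
  names(segment_genes) <- seg_df$segment
  tis_df <- utils::read.delim(p("tissue.tsv"), stringsAsFactors = FALSE)
  tissue <- stats::setNames(tis_df$tissue, tis_df$cell_line)
  manifest <- if (file.exists(p("manifest.json")))
    jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE) else NULL
  data <- omics_dataset(
    expression = read_matrix(p("expression.tsv")),
    mutation = read_matrix(p("mutation.tsv"), "binary"),
    cnv = read_matrix(p("cnv.tsv"), "binary"),
    segment_genes = segment_genes, tissue = tissue,
    tissue_levels = manifest$tissue_levels)
  list(data = data,
       pathways = read_gmt(p("pathways.gmt"), "pathway"),
       signatures = read_gmt(p("signatures.gmt"), "signature"),
       annotations = read_drug_annotations(p("drugs.tsv")),
       responses = read_response_table(p("response.tsv")),
       manifest = manifest)
}
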