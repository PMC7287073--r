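#' Validate a pipeline configuration
#'
#' Checks the configuration (a YAML path or an equivalent nested list)
#' before any computation: data source present, strategy names known,
#' requested strategies backed by the available modalities, protocol fields
#' sane. Deviations from the standard protocol (30% test split, 3-fold CV,
#' 5 repetitions) produce warnings, not errors.
#'
#' @param config Path to a YAML file or a list.
#' @return List with `errors` and `warnings` (character vectors); an empty
#'   `errors` element means the config is runnable.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0); warnings <- character(0)
  if (is.null(config$synthetic) && is.null(config$data_dir))
    errors <- c(errors, "config must provide either 'synthetic' or 'data_dir'")
  strategies <- config$strategies %||% STRATEGIES
  bad <- setdiff(strategies, STRATEGIES)
  if (length(bad))
    errors <- c(errors, sprintf("unknown strategy '%s'; valid: %s",
                                paste(bad, collapse = ", "),
                                paste(STRATEGIES, collapse = ", ")))
  families <- config$model_families %||% "en"
  if (!all(families %in% c("en", "rf")))
    errors <- c(errors, "model_families must be a subset of {en, rf}")
  if (!is.null(config$data_dir)) {
    p <- function(f) file.path(config$data_dir, f)
    if (!file.exists(p("response.tsv")))
      errors <- c(errors, sprintf("missing response table: %s", p("response.tsv")))
    if (!file.exists(p("expression.tsv")))
      errors <- c(errors, sprintf("missing expression matrix: %s", p("expression.tsv")))
    needs_bio <- any(strategies %in% c("OT", "PG", "OT+S", "PG+S"))
    if (needs_bio) {
      for (f in c("mutation.tsv", "cnv.tsv", "segment_genes.tsv", "tissue.tsv",
                  "drugs.tsv"))
        if (!file.exists(p(f)))
          errors <- c(errors, sprintf("strategy %s requires %s",
                                      paste(intersect(strategies,
                                                      c("OT", "PG", "OT+S", "PG+S")),
                                            collapse = "/"), p(f)))
    }
    if (any(strategies %in% c("PG", "PG+S")) && !file.exists(p("pathways.gmt")))
      errors <- c(errors, sprintf("PG strategies require %s", p("pathways.gmt")))
    if (any(strategies %in% c("OT+S", "PG+S")) && !file.exists(p("signatures.gmt")))
      errors <- c(errors, sprintf("+S strategies require %s", p("signatures.gmt")))
  }
  pr <- config$protocol %||% list()
  if (!is.null(pr$test_fraction) && pr$test_fraction != 0.3)
    warnings <- c(warnings, "non-standard test_fraction (standard: 0.3)")
  if (!is.null(pr$cv_folds) && pr$cv_folds != 3)
    warnings <- c(warnings, "non-standard cv_folds (standard: 3)")
  if (!is.null(pr$n_repetitions) && pr$n_repetitions != 5)
    warnings <- c(warnings, "non-standard n_repetitions (standard: 5)")
  list(errors = errors, warnings = warnings)
}

#' Run the full pipeline: data, signatures, features, models, report
#'
#' Executes every stage for every drug x strategy (x model family):
#' synthetic data generation (or loading a data directory), signature
#' scoring and filtering, per-drug feature construction, repeated-split
#' model fitting with training-only data-driven selection for the GW_SEL
#' strategies, and the evaluation report (aggregated records, baseline-
#' failure exclusions, best model per drug, pathway-level tests,
#' feature-type frequencies). All randomness flows from the single
#' configured seed, so two runs with the same config produce byte-identical
#' result tables.
#'
#' @param config YAML path or list; see [validate_config()]. Recognized
#'   top-level fields: `synthetic` (generator parameters), `data_dir`,
#'   `strategies`, `model_families`, `signature_threshold`, `protocol`,
#'   `exclusion_epsilon`, `seed`, `out_dir`, `overwrite`.
#' @param out_dir Optional override of the config's output directory; if
#'   neither is given, no files are written and results are only returned.
#' @return (Invisibly) list with `records`, `aggregated`, `excluded`,
#'   `best_models`, `pathway_tests`, `feature_frequencies`, `effects`,
#'   `skipped`, `manifest`.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  chk <- validate_config(config)
  for (w in chk$warnings) warning(w, call. = FALSE)
  if (length(chk$errors))
    stop("invalid config:\n  - ", paste(chk$errors, collapse = "\n  - "))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir
  strategies <- config$strategies %||% STRATEGIES
  families <- config$model_families %||% "en"
  protocol <- do.call(experiment_protocol,
                      c(config$protocol %||% list(), list(seed = seed)))

  if (!is.null(config$synthetic)) {
    cfg <- do.call(synthetic_config, c(config$synthetic, list(seed = seed)))
    bundle <- generate_dataset(cfg)
  } else {
    bundle <- read_dataset(config$data_dir)
  }
  data <- bundle$data
  scores <- NULL
  if (any(strategies %in% c("OT+S", "PG+S")))
    scores <- score_signatures(data$expression, bundle$signatures,
                               threshold = config$signature_threshold %||% 0.1,
                               scope = protocol$signature_scope)

  records <- list(); effects <- list(); skipped <- list()
  for (drug in bundle$annotations) {
    for (strategy in strategies) {
      fams <- if (strategy %in% c("GW_SEL_EN", "GW_SEL_RF")) "en" else families
      for (family in fams) {
        res <- run_drug(drug, strategy, data, bundle$responses, protocol,
                        pathways = bundle$pathways, scores = scores,
                        model_family = family)
        if (is_ineligible(res)) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(drug_id = res$drug_id, strategy = strategy,
                       reason = res$reason, stringsAsFactors = FALSE)
          break  # ineligibility is family-independent
        }
        records[[length(records) + 1L]] <- res$records
        mean_eff <- Reduce(`+`, lapply(res$fits, function(f) {
          e <- f$feature_effects
          e[is.na(e)] <- 0
          e
        })) / length(res$fits)
        effects[[length(effects) + 1L]] <- list(
          drug_id = drug$drug_id, strategy = res$strategy,
          pearson_r = mean(res$records$pearson_r), effects = mean_eff)
        if (strategy %in% c("GW_SEL_EN", "GW_SEL_RF")) break
      }
    }
  }
  if (!length(records)) stop("no drug was eligible for any requested strategy")
  records <- do.call(rbind, records)
  aggregated <- aggregate_records(records)
  excluded <- exclude_drugs(aggregated, config$exclusion_epsilon %||% 0.01)
  retained <- aggregated[!(aggregated$drug_id %in% excluded), , drop = FALSE]
  best <- if (nrow(retained)) best_model_per_drug(retained) else NULL
  pw_tests <- if (nrow(retained))
    pathway_comparison(retained, bundle$annotations) else NULL
  eff_table <- data.frame(
    drug_id = vapply(effects, `[[`, "", "drug_id"),
    strategy = vapply(effects, `[[`, "", "strategy"),
    pearson_r = vapply(effects, `[[`, 0, "pearson_r"),
    stringsAsFactors = FALSE)
  eff_table$effects <- lapply(effects, `[[`, "effects")
  eff_bio <- eff_table[strategy_group(eff_table$strategy) == "bio_driven" &
                         !(eff_table$drug_id %in% excluded), , drop = FALSE]
  freqs <- if (nrow(eff_bio))
    feature_type_frequencies(eff_bio, top_drugs = config$top_drugs %||% 50,
                             k_values = config$k_values %||% c(1, 5, 10)) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL

  manifest <- list(seed = seed, strategies = strategies,
                   model_families = families,
                   package_version = as.character(utils::packageVersion("priorselect")),
                   n_drugs = length(bundle$annotations),
                   n_excluded = length(excluded))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) if (!is.null(df))
      utils::write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    wt(records, "records.tsv")
    wt(aggregated, "aggregated.tsv")
    wt(data.frame(drug_id = excluded), "excluded_drugs.tsv")
    wt(best, "best_models.tsv")
    wt(pw_tests, "pathway_tests.tsv")
    wt(freqs, "feature_type_frequencies.tsv")
    wt(skipped, "skipped.tsv")
    tsvs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(tsvs))
    names(manifest$checksums) <- basename(tsvs)
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(records = records, aggregated = aggregated,
                 excluded = excluded, best_models = best,
                 pathway_tests = pw_tests, feature_frequencies = freqs,
                 effects = eff_table, skipped = skipped, manifest = manifest))
}
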