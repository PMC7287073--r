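#' Relative RMSE against the training-mean dummy baseline
#'
#' Raw test RMSE is not comparable across drugs whose response distributions
#' differ, and a near-constant response can make a useless model look
#' accurate. RelRMSE normalizes against a dummy model that always predicts
#' the training-set mean response:
#' `RelRMSE = RMSE_dummy / RMSE_model`, so 1 means no better than the
#' baseline and larger values mean actual learning.
#'
#' @param y_test Observed test responses.
#' @param y_pred Model predictions on the test set.
#' @param y_train_mean Mean response of the training set (the dummy
#'   prediction).
#' @return RelRMSE (>= 0, `Inf` with a warning when the model is exact).
#' @export
rel_rmse <- function(y_test, y_pred, y_train_mean) {
  stopifnot(length(y_test) > 0, length(y_test) == length(y_pred))
  rmse_dummy <- rmse(y_test, rep(y_train_mean, length(y_test)))
  rmse_model <- rmse(y_test, y_pred)
  if (rmse_model == 0) {
    if (rmse_dummy == 0)
      stop("undefined RelRMSE: both model and dummy RMSE are zero")
    warning("model RMSE is zero; RelRMSE is infinite")
    return(Inf)
  }
  rmse_dummy / rmse_model
}

#' Pearson correlation between predictions and observations
#'
#' Correlation with a two-sided p-value from the Student-t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param y_test,y_pred Numeric vectors (n >= 3, nonzero variance).
#' @return List with `r` and `p`.
#' @export
correlation_test <- function(y_test, y_pred) {
  if (length(y_test) < 3L) stop("need at least 3 test samples")
  if (stats::sd(y_test) == 0 || stats::sd(y_pred) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(y_pred, y_test, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Score one repetition's predictions into an evaluation record
#'
#' @param drug_id,strategy,repetition Record identity.
#' @param y_test,y_pred,y_train_mean Test observations, predictions and the
#'   dummy (training-mean) prediction.
#' @param n_samples,n_features Problem size of the fit.
#' @return One-row data frame (an evaluation record).
#' @export
evaluate_predictions <- function(drug_id, strategy, repetition, y_test, y_pred,
                                 y_train_mean, n_samples, n_features) {
  ct <- tryCatch(correlation_test(y_test, y_pred),
                 error = function(e) list(r = NA_real_, p = NA_real_))
  data.frame(drug_id = drug_id, strategy = strategy, repetition = repetition,
             n_samples = n_samples, n_features = n_features,
             rmse = rmse(y_test, y_pred),
             rel_rmse = rel_rmse(y_test, y_pred, y_train_mean),
             pearson_r = ct$r, p_value = ct$p,
             stringsAsFactors = FALSE)
}

#' Average evaluation records over repetitions
#'
#' @param records Data frame of per-repetition records.
#' @return One row per (drug, strategy) with metrics averaged over
#'   repetitions.
#' @export
aggregate_records <- function(records) {
  agg <- stats::aggregate(
    records[, c("n_samples", "n_features", "rmse", "rel_rmse",
                "pearson_r", "p_value")],
    by = records[, c("drug_id", "strategy")],
    FUN = mean)
  agg$n_repetitions <- stats::aggregate(records$repetition,
                                        by = records[, c("drug_id", "strategy")],
                                        FUN = length)$x
  agg[order(agg$drug_id, agg$strategy), , drop = FALSE]
}

#' Exclude drugs whose best model never beats the dummy baseline
#'
#' A drug is excluded when even its best strategy's mean RelRMSE fails to
#' exceed 1 by more than `epsilon` — for such compounds the models only
#' capture the mean response and no learning occurred.
#'
#' @param aggregated Output of [aggregate_records()].
#' @param epsilon Slack above the baseline of 1 (default 0.01).
#' @return Character vector of excluded drug ids.
#' @export
exclude_drugs <- function(aggregated, epsilon = 0.01) {
  best <- tapply(aggregated$rel_rmse, aggregated$drug_id, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) -Inf else max(v)   # no scorable strategy = baseline failure
  })
  names(best)[best <= 1 + epsilon]
}

#' Best strategy per drug by mean test correlation
#'
#' Ties are broken in favor of fewer features, then lexical strategy name.
#'
#' @param aggregated Output of [aggregate_records()].
#' @return Data frame: `drug_id`, `strategy`, `pearson_r`, `n_features`.
#' @export
best_model_per_drug <- function(aggregated, ...) {
  out <- do.call(rbind, lapply(split(aggregated, aggregated$drug_id), function(d) {
    d <- d[order(-d$pearson_r, d$n_features, d$strategy), , drop = FALSE]
    d[1L, c("drug_id", "strategy", "pearson_r", "n_features"), drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

strategy_group <- function(strategy) {
  ifelse(grepl("^GW", strategy), "genome_wide", "bio_driven")
}

#' Pathway-level comparison of genome-wide vs biologically driven models
#'
#' For each target-pathway class: per drug, take the best test correlation
#' within the genome-wide group (GW, GW_SEL_*) and within the biologically
#' driven group (OT, PG, OT+S, PG+S); compare the two sets of per-drug
#' values with a one-sided Mann-Whitney-Wilcoxon test in the direction of
#' the larger group median. Pathways with fewer than 2 drugs carrying both
#' groups are skipped.
#'
#' @param aggregated Output of [aggregate_records()] (excluded drugs should
#'   be removed first).
#' @param annotations Named list of [drug_annotation()].
#' @return Data frame: pathway, n_drugs, medians, favored direction,
#'   one-sided p-value.
#' @export
pathway_comparison <- function(aggregated, annotations) {
  pw <- vapply(annotations, `[[`, "", "target_pathway")
  aggregated$group <- strategy_group(aggregated$strategy)
  per_drug <- do.call(rbind, lapply(split(aggregated, aggregated$drug_id),
                                    function(d) {
    gw <- d$pearson_r[d$group == "genome_wide"]
    bio <- d$pearson_r[d$group == "bio_driven"]
    gw <- gw[!is.na(gw)]; bio <- bio[!is.na(bio)]
    if (!length(gw) || !length(bio)) return(NULL)
    data.frame(drug_id = d$drug_id[1L], gw = max(gw), bio = max(bio),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_drug)) return(NULL)
  per_drug$pathway <- unname(pw[per_drug$drug_id])
  out <- lapply(split(per_drug, per_drug$pathway), function(g) {
    if (nrow(g) < 2L) {
      return(data.frame(pathway = g$pathway[1L], n_drugs = nrow(g),
                        median_gw = stats::median(g$gw),
                        median_bio = stats::median(g$bio),
                        favored = NA_character_, p_value = NA_real_,
                        note = "skipped: <2 drugs", stringsAsFactors = FALSE))
    }
    favored <- if (stats::median(g$gw) >= stats::median(g$bio))
      "genome_wide" else "bio_driven"
    alt <- if (favored == "genome_wide") "greater" else "less"
    wt <- suppressWarnings(stats::wilcox.test(g$gw, g$bio, alternative = alt,
                                              paired = FALSE))
    data.frame(pathway = g$pathway[1L], n_drugs = nrow(g),
               median_gw = stats::median(g$gw),
               median_bio = stats::median(g$bio),
               favored = favored, p_value = wt$p.value, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Feature-type frequencies among top-ranked features
#'
#' Restricts to the `top_drugs` drugs with the best biologically driven
#' performance, takes each of their biologically driven models' top-k
#' features by effect magnitude (absolute standardized coefficient for
#' elastic net, impurity importance for forests), and tabulates the
#' proportion of each feature type among them, per k. Models with fewer
#' than k features contribute all of theirs.
#'
#' @param effects_table Data frame with one row per model:
#'   `drug_id`, `strategy`, `pearson_r` and a list-column `effects` of named
#'   numeric vectors (names are `type:source` feature keys).
#' @param top_drugs Number of best drugs to keep (default 50).
#' @param k_values Feature-count cutoffs to tabulate.
#' @return Data frame: k, feature type, frequency (summing to 1 per k).
#' @export
feature_type_frequencies <- function(effects_table, top_drugs = 50,
                                     k_values = c(1, 5, 10)) {
  bio <- effects_table[strategy_group(effects_table$strategy) == "bio_driven", ,
                       drop = FALSE]
  if (!nrow(bio)) stop("no biologically driven models in effects table")
  best_r <- tapply(bio$pearson_r, bio$drug_id, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) -Inf else max(v)
  })
  keep_drugs <- names(sort(best_r, decreasing = TRUE))
  keep_drugs <- utils::head(keep_drugs, top_drugs)
  bio <- bio[bio$drug_id %in% keep_drugs, , drop = FALSE]
  out <- list()
  for (k in k_values) {
    types <- unlist(lapply(bio$effects, function(eff) {
      top <- names(sort(eff, decreasing = TRUE))[seq_len(min(k, length(eff)))]
      sub(":.*$", "", top)
    }), use.names = FALSE)
    tab <- table(factor(types, levels = c("expression", "mutation", "cnv",
                                          "tissue", "signature")))
    out[[as.character(k)]] <- data.frame(
      k = k, type = names(tab), frequency = as.numeric(tab) / sum(tab),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
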