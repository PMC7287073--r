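#' Experiment protocol
#'
#' The repeated train/test protocol used for every drug and strategy: a
#' random split with 30% of samples held out for testing, hyperparameter
#' tuning by 3-fold cross-validation on the training part (MSE score), and
#' the whole procedure repeated five times with different splits. Metrics
#' are averaged over the repetitions downstream.
#'
#' @param test_fraction Held-out fraction (default 0.3).
#' @param cv_folds Tuning CV folds (default 3).
#' @param n_repetitions Number of independent splits (default 5).
#' @param seed Integer master seed; split `r` uses a substream derived from
#'   `(seed, r)`.
#' @param en_alpha_grid Elastic-net mixing grid (1 = lasso).
#' @param en_nlambda Penalty-path length per mixing value.
#' @param rf_num_trees Trees per forest (fixed, not tuned).
#' @param rf_depth_grid Tree depth grid; 0 = unlimited.
#' @param rf_mtry_grid Features-per-split grid: `"sqrt"`, `"third"`, `"all"`.
#' @param sel_n_subsamples,sel_k_grid Stability-selection subsample count
#'   and the candidate feature counts for [choose_k()] in the GW_SEL
#'   strategies.
#' @param signature_scope Scope for signature z-scoring, `"global"`
#'   (whole-dataset convention) or `"train_only"`.
#' @export
experiment_protocol <- function(test_fraction = 0.3, cv_folds = 3,
                                n_repetitions = 5, seed = 1L,
                                en_alpha_grid = seq(0.1, 1, by = 0.1),
                                en_nlambda = 30,
                                rf_num_trees = 500,
                                rf_depth_grid = c(0, 10, 20),
                                rf_mtry_grid = c("sqrt", "third", "all"),
                                sel_n_subsamples = 100,
                                sel_k_grid = c(10, 30, 70, 150, 500),
                                signature_scope = "global") {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2,
            n_repetitions >= 1, length(en_alpha_grid) >= 1)
  structure(list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed),
                 en_alpha_grid = en_alpha_grid, en_nlambda = en_nlambda,
                 rf_num_trees = rf_num_trees, rf_depth_grid = rf_depth_grid,
                 rf_mtry_grid = rf_mtry_grid,
                 sel_n_subsamples = sel_n_subsamples, sel_k_grid = sel_k_grid,
                 signature_scope = signature_scope),
            class = "experiment_protocol")
}

#' Deterministic train/test split
#'
#' @param sample_ids Character vector of sample ids (>= 10).
#' @param protocol An [experiment_protocol()].
#' @param repetition Repetition index (1-based); the split is a pure
#'   function of `(protocol$seed, repetition)`.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive,
#'   `|test| = round(test_fraction * n)`).
#' @export
split_samples <- function(sample_ids, protocol, repetition = 1L) {
  n <- length(sample_ids)
  if (n < 10L) stop("too few samples to split (need >= 10)")
  n_test <- round(protocol$test_fraction * n)
  set.seed(substream_seed(protocol$seed, repetition))
  test <- sort(sample(sample_ids, n_test))
  list(train = setdiff(sample_ids, test), test = test)
}

# Standardize continuous columns by training statistics; binary 0/1 columns
# are left untouched; constant columns are dropped with a warning.
standardize_train_test <- function(x_train, x_test) {
  is_bin <- apply(x_train, 2L, is_binary01)
  sds <- apply(x_train, 2L, stats::sd)
  drop <- sds == 0 & !is_bin
  if (any(drop)) {
    warning(sprintf("dropping %d constant column(s)", sum(drop)))
    x_train <- x_train[, !drop, drop = FALSE]
    x_test <- x_test[, !drop, drop = FALSE]
    is_bin <- is_bin[!drop]; sds <- sds[!drop]
  }
  cont <- !is_bin
  if (any(cont)) {
    mu <- colMeans(x_train[, cont, drop = FALSE])
    s <- sds[cont]
    s[s == 0] <- 1
    x_train[, cont] <- sweep(sweep(x_train[, cont, drop = FALSE], 2L, mu), 2L, s, `/`)
    x_test[, cont] <- sweep(sweep(x_test[, cont, drop = FALSE], 2L, mu), 2L, s, `/`)
  }
  list(train = x_train, test = x_test)
}

fit_result <- function(family, hyperparameters, predictions, feature_effects,
                       train_ids, test_ids, y_train_mean) {
  structure(list(model_family = family, hyperparameters = hyperparameters,
                 predictions = predictions, feature_effects = feature_effects,
                 train_ids = train_ids, test_ids = test_ids,
                 y_train_mean = y_train_mean),
            class = "fit_result")
}

#' Fit a tuned elastic-net regression
#'
#' Continuous features are z-scored with training statistics (applied
#' unchanged to the test matrix); binary features stay 0/1. The mixing
#' parameter and penalty strength are tuned by k-fold CV minimizing MSE,
#' the model is refit on the full training set, and feature effects are the
#' absolute coefficients on the standardized scale.
#'
#' @param x_train,y_train Training design matrix and response.
#' @param protocol An [experiment_protocol()] (grids, folds, seed).
#' @param x_test Optional test matrix for predictions.
#' @return A `fit_result`.
#' @export
fit_en <- function(x_train, y_train, protocol, x_test = NULL) {
  x_train <- as_values(x_train)
  if (stats::sd(y_train) == 0) stop("constant response; nothing to fit")
  if (is.null(x_test))
    x_test <- x_train[0, , drop = FALSE]
  else x_test <- as_values(x_test)
  st <- standardize_train_test(x_train, x_test)
  xtr <- st$train; xte <- st$test
  if (ncol(xtr) == 0L) stop("no usable feature columns")
  if (ncol(xtr) == 1L) {               # OLS fallback; glmnet needs >= 2 columns
    b <- stats::lm.fit(cbind(1, xtr), y_train)$coefficients
    pred <- as.numeric(cbind(1, xte) %*% b)
    return(fit_result("en", list(alpha = NA, lambda = 0),
                      stats::setNames(pred, rownames(xte)),
                      stats::setNames(abs(b[-1L]), colnames(xtr)),
                      rownames(xtr), rownames(xte), mean(y_train)))
  }
  set.seed(substream_seed(protocol$seed, 31))
  foldid <- sample(rep_len(seq_len(protocol$cv_folds), nrow(xtr)))
  best <- NULL
  for (a in protocol$en_alpha_grid) {
    cv <- glmnet::cv.glmnet(xtr, y_train, alpha = a, foldid = foldid,
                            nlambda = protocol$en_nlambda,
                            type.measure = "mse", standardize = FALSE)
    score <- min(cv$cvm)
    if (is.null(best) || score < best$score)
      best <- list(alpha = a, lambda = cv$lambda.min, score = score)
  }
  fit <- glmnet::glmnet(xtr, y_train, alpha = best$alpha,
                        lambda = best$lambda, standardize = FALSE)
  coefs <- as.numeric(stats::coef(fit))[-1L]
  pred <- if (nrow(xte)) as.numeric(stats::predict(fit, xte)) else numeric(0)
  fit_result("en", list(alpha = best$alpha, lambda = best$lambda),
             stats::setNames(pred, rownames(xte)),
             stats::setNames(abs(coefs), colnames(xtr)),
             rownames(xtr), rownames(xte), mean(y_train))
}

#' Fit a tuned random-forest regression
#'
#' Tree count is fixed; maximum depth and features-per-split are tuned by
#' k-fold CV minimizing MSE. Feature effects are impurity-decrease
#' importances from the refit on the full training set.
#'
#' @inheritParams fit_en
#' @export
fit_rf <- function(x_train, y_train, protocol, x_test = NULL) {
  x_train <- as_values(x_train)
  if (stats::sd(y_train) == 0) stop("constant response; nothing to fit")
  if (is.null(x_test)) x_test <- x_train[0, , drop = FALSE]
  else x_test <- as_values(x_test)
  p <- ncol(x_train)
  mtry_of <- function(kind) switch(kind,
    sqrt = max(1L, floor(sqrt(p))),
    third = max(1L, floor(p / 3)),
    all = p)
  grid <- expand.grid(depth = protocol$rf_depth_grid,
                      mtry = protocol$rf_mtry_grid,
                      stringsAsFactors = FALSE)
  set.seed(substream_seed(protocol$seed, 32))
  foldid <- sample(rep_len(seq_len(protocol$cv_folds), nrow(x_train)))
  cv_score <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(protocol$cv_folds), function(f) {
      tr <- foldid != f
      fit <- ranger::ranger(x = x_train[tr, , drop = FALSE], y = y_train[tr],
                            num.trees = protocol$rf_num_trees,
                            max.depth = grid$depth[i],
                            mtry = mtry_of(grid$mtry[i]),
                            seed = substream_seed(protocol$seed, 100 + i),
                            num.threads = 1)
      pred <- stats::predict(fit, data = x_train[!tr, , drop = FALSE])$predictions
      mean((pred - y_train[!tr])^2)
    }, numeric(1)))
  }, numeric(1))
  bi <- which.min(cv_score)
  fit <- ranger::ranger(x = x_train, y = y_train,
                        num.trees = protocol$rf_num_trees,
                        max.depth = grid$depth[bi], mtry = mtry_of(grid$mtry[bi]),
                        importance = "impurity",
                        seed = substream_seed(protocol$seed, 33),
                        num.threads = 1)
  pred <- if (nrow(x_test))
    stats::predict(fit, data = x_test)$predictions else numeric(0)
  imp <- fit$variable.importance
  fit_result("rf", list(num_trees = protocol$rf_num_trees,
                        depth = grid$depth[bi], mtry = mtry_of(grid$mtry[bi])),
             stats::setNames(pred, rownames(x_test)),
             imp, rownames(x_train), rownames(x_test), mean(y_train))
}

#' Run the full protocol for one drug and strategy
#'
#' Builds the strategy's feature matrix, then for every repetition: split
#' the samples, optionally run data-driven selection on the training
#' partition only (GW_SEL strategies), fit the model family, predict the
#' held-out samples and score them. Selection and standardization never see
#' test data; signature activity follows the protocol's configured scope.
#'
#' @param drug A [drug_annotation()].
#' @param strategy Strategy name (see [strategy_spec()]).
#' @param data An [omics_dataset()].
#' @param responses A [response_table()].
#' @param protocol An [experiment_protocol()].
#' @param pathways,scores Pathway collection and `signature_scores`, needed
#'   by the PG and +S strategies.
#' @param model_family `"en"` or `"rf"` for the non-SEL strategies (the SEL
#'   strategies imply their family).
#' @return List with `records` (one row per repetition: n_samples,
#'   n_features, rmse, rel_rmse, pearson_r, p_value) and `fits` (the
#'   `fit_result`s), or a `drug_ineligible` marker.
#' @export
run_drug <- function(drug, strategy, data, responses, protocol,
                     pathways = NULL, scores = NULL,
                     model_family = c("en", "rf")) {
  spec <- strategy_spec(strategy)
  family <- switch(spec$selection, stability = "en", forest_importance = "rf",
                   match.arg(model_family))
  fm <- build_features(spec, drug, data, responses, pathways, scores)
  if (is_ineligible(fm)) return(fm)
  if (nrow(fm$values) < 10L)
    return(ineligible(drug$drug_id, "fewer than 10 responded samples"))
  resp <- responses[responses$drug_id == drug$drug_id, ]
  y_all <- stats::setNames(resp$auc, resp$cell_line)[fm$sample_ids]
  label <- if (spec$selection == "none")
    paste(spec$name, toupper(family), sep = "_") else spec$name
  fits <- vector("list", protocol$n_repetitions)
  recs <- vector("list", protocol$n_repetitions)
  for (r in seq_len(protocol$n_repetitions)) {
    sp <- split_samples(fm$sample_ids, protocol, r)
    xtr <- fm$values[sp$train, , drop = FALSE]
    xte <- fm$values[sp$test, , drop = FALSE]
    ytr <- y_all[sp$train]; yte <- y_all[sp$test]
    rep_protocol <- protocol
    rep_protocol$seed <- substream_seed(protocol$seed, 1000 + r)
    if (spec$selection != "none") {
      sel <- if (spec$selection == "stability")
        stability_select(xtr, ytr, n_subsamples = protocol$sel_n_subsamples,
                         seed = substream_seed(protocol$seed, 2000 + r))
      else forest_importance_select(xtr, ytr, n_trees = protocol$rf_num_trees,
                                    seed = substream_seed(protocol$seed, 2000 + r))
      sel <- choose_k(sel, xtr, ytr, protocol$sel_k_grid, family,
                      protocol$cv_folds,
                      seed = substream_seed(protocol$seed, 3000 + r))
      keep <- top_features(sel)
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
    }
    fit <- if (family == "en") fit_en(xtr, ytr, rep_protocol, xte)
           else fit_rf(xtr, ytr, rep_protocol, xte)
    fits[[r]] <- fit
    recs[[r]] <- evaluate_predictions(
      drug_id = drug$drug_id, strategy = label, repetition = r,
      y_test = yte, y_pred = fit$predictions, y_train_mean = fit$y_train_mean,
      n_samples = length(fm$sample_ids), n_features = ncol(xtr))
  }
  list(records = do.call(rbind, recs), fits = fits, strategy = label)
}
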