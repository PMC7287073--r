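as_values <- function(X) {
  if (inherits(X, "feature_matrix")) X$values else X
}

selection_result <- function(ranked, scores, method, k = NA_integer_,
                             details = list()) {
  stopifnot(length(ranked) == length(scores), !is.unsorted(rev(scores)))
  structure(list(ranked_features = ranked,
                 scores = stats::setNames(scores, ranked),
                 k = k, method = method, details = details),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s, %d candidates, k=%s\n",
              x$method, length(x$ranked_features),
              if (is.na(x$k)) "unset" else x$k))
  invisible(x)
}

#' Stability selection on genome-wide expression
#'
#' Ranks features by how robustly the lasso picks them: the lasso is fit on
#' many random half-samples over a grid of penalty strengths, and a
#' feature's score is the maximum, over the penalty grid, of the fraction of
#' subsamples in which its coefficient is nonzero. Ties are broken by mean
#' absolute coefficient, then feature id.
#'
#' @param X [feature_matrix()] or numeric matrix (samples x features).
#' @param y Numeric response (dose-response AUC).
#' @param n_subsamples Number of subsamples (default 100).
#' @param lambda_grid Lasso penalty grid; default 30 log-spaced values from
#'   the full-data lasso path.
#' @param subsample_fraction Fraction of samples per draw (default 0.5).
#' @param replace Draw subsamples with replacement (default FALSE: classical
#'   without-replacement half-sampling).
#' @param seed Integer seed; results are deterministic given it.
#' @return A `selection_result` with per-feature selection frequencies in
#'   \[0, 1\].
#' @export
stability_select <- function(X, y, n_subsamples = 100, lambda_grid = NULL,
                             subsample_fraction = 0.5, replace = FALSE,
                             seed = 1L) {
  x <- as_values(X)
  n <- nrow(x); p <- ncol(x)
  if (n < 20L) stop("stability selection needs >= 20 samples")
  if (stats::sd(y) == 0) stop("degenerate response: zero variance")
  if (p == 1L) {
    fit <- stats::lm.fit(cbind(1, x), y)
    return(selection_result(colnames(x), 1.0, "stability",
                            details = list(single = TRUE,
                                           coef = abs(fit$coefficients[2L]))))
  }
  if (is.null(lambda_grid)) {
    path <- glmnet::glmnet(x, y, alpha = 1, nlambda = 30)
    lambda_grid <- path$lambda
  }
  nl <- length(lambda_grid)
  if (!nl) stop("empty penalty grid")
  sel_count <- matrix(0, p, nl)
  abs_sum <- numeric(p)
  m <- max(2L, floor(subsample_fraction * n))
  set.seed(seed)
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, m, replace = replace)
    fit <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx], alpha = 1,
                          lambda = lambda_grid)
    beta <- as.matrix(fit$beta)
    if (ncol(beta) < nl) {  # glmnet may truncate the path; pad with zeros
      beta <- cbind(beta, matrix(0, p, nl - ncol(beta)))
    }
    sel_count <- sel_count + (beta != 0)
    abs_sum <- abs_sum + rowSums(abs(beta))
  }
  freq <- sel_count / n_subsamples
  score <- apply(freq, 1L, max)
  mean_abs <- abs_sum / (n_subsamples * nl)
  ids <- colnames(x) %||% sprintf("F%05d", seq_len(p))
  if (all(score == 0))
    warning("no feature was ever selected; ranking by mean |coefficient|")
  ord <- order(-score, -mean_abs, ids)
  selection_result(ids[ord], score[ord], "stability",
                   details = list(mean_abs_coef = stats::setNames(mean_abs, ids),
                                  lambda_grid = lambda_grid))
}

#' Random-forest importance ranking
#'
#' Fits a random-forest regressor and ranks features by impurity-decrease
#' importance, normalized to sum to 1; ties are broken by feature id.
#'
#' @inheritParams stability_select
#' @param n_trees Number of trees (default 500).
#' @export
forest_importance_select <- function(X, y, n_trees = 500, seed = 1L) {
  x <- as_values(X)
  if (nrow(x) < 20L) stop("forest importance selection needs >= 20 samples")
  if (stats::sd(y) == 0) stop("degenerate response: zero variance")
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- pmax(fit$variable.importance, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ids <- names(imp)
  ord <- order(-imp, ids)
  selection_result(ids[ord], unname(imp[ord]), "forest_importance")
}

#' Choose the number of features by inner cross-validation
#'
#' For each candidate k, evaluates the downstream model family on the top-k
#' ranked features by cross-validated mean squared error and picks the k
#' with the smallest mean CV MSE (ties go to the smaller k). The chosen
#' top-k set is always a prefix of the ranking.
#'
#' @param selection A `selection_result`.
#' @param X,y Training data (the same candidates the ranking was computed
#'   on).
#' @param k_grid Candidate feature counts; values above the number of
#'   candidates are clipped.
#' @param model_family `"en"` (elastic net) or `"rf"` (random forest).
#' @param cv_folds Inner CV folds (default 3).
#' @param seed Integer seed.
#' @return The `selection_result` with `k` set and CV details attached.
#' @export
choose_k <- function(selection, X, y, k_grid, model_family = c("en", "rf"),
                     cv_folds = 3, seed = 1L) {
  model_family <- match.arg(model_family)
  stopifnot(inherits(selection, "selection_result"))
  if (!length(k_grid)) stop("empty k grid")
  x <- as_values(X)
  x <- x[, selection$ranked_features, drop = FALSE]
  k_grid <- sort(unique(pmin(as.integer(k_grid), ncol(x))))
  set.seed(substream_seed(seed, 99))
  foldid <- sample(rep_len(seq_len(cv_folds), nrow(x)))
  cv_mse <- vapply(k_grid, function(k) {
    xk <- x[, seq_len(k), drop = FALSE]
    mse <- vapply(seq_len(cv_folds), function(f) {
      tr <- foldid != f
      if (model_family == "en") {
        if (k == 1L) {
          b <- stats::lm.fit(cbind(1, xk[tr, , drop = FALSE]), y[tr])$coefficients
          pred <- cbind(1, xk[!tr, , drop = FALSE]) %*% b
        } else {
          fit <- glmnet::glmnet(xk[tr, , drop = FALSE], y[tr], alpha = 0.5,
                                nlambda = 20)
          # score the path on the held-out fold; take the best lambda's MSE
          preds <- stats::predict(fit, xk[!tr, , drop = FALSE])
          return(min(colMeans((preds - y[!tr])^2)))
        }
      } else {
        fit <- ranger::ranger(x = xk[tr, , drop = FALSE], y = y[tr],
                              num.trees = 200, seed = substream_seed(seed, f),
                              num.threads = 1)
        pred <- stats::predict(fit, data = xk[!tr, , drop = FALSE])$predictions
      }
      mean((pred - y[!tr])^2)
    }, numeric(1))
    mean(mse)
  }, numeric(1))
  best <- k_grid[which.min(cv_mse)]   # which.min takes the first = smallest k
  selection$k <- best
  selection$details$k_grid <- k_grid
  selection$details$cv_mse <- stats::setNames(cv_mse, k_grid)
  selection
}

#' Top-k features of a sized selection
#' @param selection A `selection_result` with `k` set (or `k` supplied).
#' @param k Optional override.
#' @export
top_features <- function(selection, k = selection$k) {
  stopifnot(!is.na(k), k >= 1)
  utils::head(selection$ranked_features, k)
}
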