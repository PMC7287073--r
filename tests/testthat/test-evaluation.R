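test_that("the dummy predictor scores RelRMSE 1 exactly against itself", {
  set.seed(40)
  for (i in 1:10) {
    y_train <- runif(sample(20:100, 1))
    y_test <- runif(sample(5:50, 1))
    m <- mean(y_train)
    expect_identical(rel_rmse(y_test, rep(m, length(y_test)), m), 1)
  }
})

test_that("RelRMSE is a plain RMSE ratio with the documented edge cases", {
  y <- c(0.2, 0.4, 0.6, 0.8)
  m <- 0.5
  # predictions with exactly half the dummy's RMSE
  pred <- y + (m - y) / 2
  expect_equal(rel_rmse(y, pred, m), 2.0)
  # independent two-RMSE recomputation on a fitted-model-like vector
  set.seed(41)
  y2 <- runif(30); p2 <- y2 + rnorm(30, 0, 0.1); m2 <- 0.45
  direct <- sqrt(mean((y2 - m2)^2)) / sqrt(mean((y2 - p2)^2))
  expect_equal(rel_rmse(y2, p2, m2), direct, tolerance = 1e-12)
  expect_warning(v <- rel_rmse(y, y, m), "infinite")
  expect_identical(v, Inf)
  expect_error(rel_rmse(c(0.5, 0.5), c(0.5, 0.5), 0.5), "undefined")
  # RelRMSE > 1 iff the model beats the dummy
  expect_gt(rel_rmse(y, pred, m), 1)
  expect_lt(rel_rmse(y, rev(y), m), 1)
})

test_that("correlation test matches the t-distribution and rejects degenerate input", {
  y <- runif(10)
  expect_equal(correlation_test(y, y)$r, 1)
  expect_equal(correlation_test(y, -y)$r, -1)
  set.seed(42)
  a <- rnorm(25); b <- a + rnorm(25)
  ct <- correlation_test(a, b)
  r <- cor(a, b); tval <- r * sqrt(23 / (1 - r^2))
  expect_equal(ct$p, 2 * pt(-abs(tval), 23), tolerance = 1e-12)
  expect_error(correlation_test(a, rep(1, 25)), "zero variance")
  expect_error(correlation_test(a[1:2], b[1:2]), "at least 3")
})

agg_row <- function(drug, strategy, rel = 1.5, r = 0.5, nf = 10)
  data.frame(drug_id = drug, strategy = strategy, n_samples = 100,
             n_features = nf, rmse = 0.1, rel_rmse = rel, pearson_r = r,
             p_value = 0.01, n_repetitions = 5)

test_that("drugs are excluded exactly when no strategy beats the baseline", {
  agg <- rbind(agg_row("d1", "OT_EN", rel = 1.0),
               agg_row("d1", "GW_EN", rel = 1.005),
               agg_row("d2", "OT_EN", rel = 0.9),
               agg_row("d2", "GW_EN", rel = 1.5),
               agg_row("d3", "OT_EN", rel = 1.011))
  ex <- exclude_drugs(agg, epsilon = 0.01)
  expect_setequal(ex, "d1")
  expect_setequal(exclude_drugs(agg, epsilon = 0.02), c("d1", "d3"))
})

test_that("best model per drug maximizes correlation with size/lexical tie-breaks", {
  agg <- rbind(agg_row("d1", "GW_EN", r = 0.6, nf = 17737),
               agg_row("d1", "OT_EN", r = 0.6, nf = 7),
               agg_row("d1", "PG_EN", r = 0.4, nf = 300),
               agg_row("d2", "B_EN", r = 0.2, nf = 5),
               agg_row("d2", "A_EN", r = 0.2, nf = 5))
  best <- best_model_per_drug(agg)
  expect_equal(best$strategy[best$drug_id == "d1"], "OT_EN")  # fewer features
  expect_equal(best$strategy[best$drug_id == "d2"], "A_EN")   # lexical
  # permutation invariance to record order
  perm <- agg[sample(nrow(agg)), ]
  expect_equal(best_model_per_drug(perm), best)
})

test_that("exhaustive argmax check on a 4-drug x 7-strategy table", {
  set.seed(43)
  strategies <- c("OT_EN", "PG_EN", "OT+S_EN", "PG+S_EN", "GW_EN",
                  "GW_SEL_EN", "GW_SEL_RF")
  agg <- do.call(rbind, lapply(sprintf("d%d", 1:4), function(d)
    do.call(rbind, lapply(strategies, function(s)
      agg_row(d, s, r = round(runif(1), 3), nf = sample(10:1000, 1))))))
  best <- best_model_per_drug(agg)
  for (d in sprintf("d%d", 1:4)) {
    sub <- agg[agg$drug_id == d, ]
    expect_equal(best$pearson_r[best$drug_id == d], max(sub$pearson_r))
  }
})

test_that("pathway comparison tests the larger-median direction per pathway", {
  ann <- list(d1 = drug_annotation("d1", "A", "pwX"),
              d2 = drug_annotation("d2", "B", "pwX"),
              d3 = drug_annotation("d3", "C", "pwX"),
              d4 = drug_annotation("d4", "D", "pwY"))
  mk <- function(d, gw, bio) rbind(agg_row(d, "GW_EN", r = gw),
                                   agg_row(d, "OT_EN", r = bio))
  agg <- rbind(mk("d1", 0.8, 0.2), mk("d2", 0.7, 0.1), mk("d3", 0.9, 0.3),
               mk("d4", 0.5, 0.5))
  out <- pathway_comparison(agg, ann)
  x <- out[out$pathway == "pwX", ]
  expect_equal(x$favored, "genome_wide")
  expect_equal(x$n_drugs, 3)
  direct <- wilcox.test(c(0.8, 0.7, 0.9), c(0.2, 0.1, 0.3),
                        alternative = "greater")$p.value
  expect_equal(x$p_value, direct)
  expect_equal(out$note[out$pathway == "pwY"], "skipped: <2 drugs")
})

test_that("identical group values give no one-sided significance", {
  ann <- lapply(sprintf("d%d", 1:4), function(d)
    drug_annotation(d, "A", "pwZ"))
  names(ann) <- sprintf("d%d", 1:4)
  agg <- do.call(rbind, lapply(names(ann), function(d)
    rbind(agg_row(d, "GW_EN", r = 0.5), agg_row(d, "OT_EN", r = 0.5))))
  out <- pathway_comparison(agg, ann)
  expect_gte(out$p_value, 0.5)
})

test_that("feature-type frequencies normalize per k and respect model size", {
  eff <- data.frame(drug_id = c("d1", "d2"), strategy = "OT_EN",
                    pearson_r = c(0.8, 0.6))
  eff$effects <- list(
    c("mutation:A" = 5, "expression:A" = 1, "tissue:t1" = 0.1),
    c("mutation:B" = 3, "expression:B" = 2))
  fr <- feature_type_frequencies(eff, top_drugs = 50, k_values = c(1, 10))
  k1 <- fr[fr$k == 1, ]
  expect_equal(k1$frequency[k1$type == "mutation"], 1)
  for (k in c(1, 10))
    expect_equal(sum(fr$frequency[fr$k == k]), 1)
  # k exceeding a model's feature count takes all its features
  k10 <- fr[fr$k == 10, ]
  expect_equal(k10$frequency[k10$type == "mutation"], 2 / 5)
  # genome-wide models are ignored; purely GW input errors
  gw <- eff; gw$strategy <- "GW_EN"
  expect_error(feature_type_frequencies(gw), "no biologically driven")
})

test_that("aggregation averages metrics over repetitions per drug and strategy", {
  rec <- rbind(
    evaluate_predictions("d1", "OT_EN", 1, c(0.2, 0.5, 0.9), c(0.25, 0.5, 0.8),
                         0.55, 10, 3),
    evaluate_predictions("d1", "OT_EN", 2, c(0.3, 0.6, 0.9), c(0.3, 0.55, 0.95),
                         0.6, 10, 3))
  agg <- aggregate_records(rec)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$rmse, mean(rec$rmse))
  expect_equal(agg$rel_rmse, mean(rec$rel_rmse))
  expect_equal(agg$n_repetitions, 2L)
})
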