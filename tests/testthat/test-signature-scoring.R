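test_that("coherence score handles perfectly coherent and anti-coherent pairs", {
  x <- rnorm(20)
  expect_equal(coherence_score(rbind(x, x)), 1.0)
  expect_equal(coherence_score(rbind(x, -x)), -1.0)
  # affine copies are still perfectly correlated
  expect_equal(coherence_score(rbind(x, 3 * x + 7)), 1.0)
})

test_that("vectorized coherence equals the brute-force pairwise loop", {
  set.seed(100)
  for (rep in 1:20) {
    i <- sample(6:20, 1); n <- sample(20:50, 1)
    X <- matrix(rnorm(i * n), i, n)
    expect_equal(coherence_score(X), brute_force_cs(X), tolerance = 1e-10)
  }
})

test_that("zero-variance genes are excluded with a warning; no valid pair errors", {
  X <- rbind(rnorm(10), rnorm(10), rep(1, 10))
  expect_warning(cs <- coherence_score(X), "zero-variance")
  expect_equal(cs, suppressWarnings(coherence_score(X[1:2, ])))
  expect_error(suppressWarnings(coherence_score(rbind(rep(1, 10), rep(2, 10)))),
               "fewer than 2")
})

test_that("sample-axis reading is available as a non-default option", {
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(coherence_score(X, axis = "samples"),
               brute_force_cs(t(X)), tolerance = 1e-10)
})

test_that("single-gene signature activity is exactly that gene's z-score", {
  set.seed(7)
  expr <- matrix(rnorm(30), 10, 3,
                 dimnames = list(sprintf("s%d", 1:10), c("A", "B", "C")))
  act <- signature_activity(expr, gene_set_collection(list(solo = "B"),
                                                      "signature"))
  expect_equal(unname(act[, "solo"]),
               unname((expr[, "B"] - mean(expr[, "B"])) / sd(expr[, "B"])))
})

test_that("global-scope activity has mean zero per signature", {
  set.seed(8)
  expr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("s%d", 1:20), sprintf("g%d", 1:10)))
  sets <- gene_set_collection(list(S1 = c("g1", "g2", "g3"),
                                   S2 = sprintf("g%d", 4:10)), "signature")
  act <- signature_activity(expr, sets)
  expect_equal(unname(colMeans(act)), c(0, 0), tolerance = 1e-12)
})

test_that("3-gene activity on a small matrix matches hand-computed z-score means", {
  expr <- matrix(c(1, 2, 3, 4,   10, 10, 20, 40,   5, 4, 3, 2), 4, 3,
                 dimnames = list(sprintf("s%d", 1:4), c("A", "B", "C")))
  act <- signature_activity(expr, gene_set_collection(list(S = c("A", "B", "C")),
                                                      "signature"))
  manual <- rowMeans(scale(expr))   # independent route via base scale()
  expect_equal(unname(act[, "S"]), unname(manual), tolerance = 1e-12)
})

test_that("missing and zero-variance genes are dropped, not fatal", {
  set.seed(9)
  expr <- cbind(matrix(rnorm(40), 10, 4), flat = rep(2, 10))
  colnames(expr) <- c("A", "B", "C", "D", "flat")
  rownames(expr) <- sprintf("s%d", 1:10)
  sets <- gene_set_collection(list(S1 = c("A", "B", "absent"),
                                   S2 = c("flat", "C"),
                                   S3 = "flat"), "signature")
  expect_warning(
    act <- withCallingHandlers(signature_activity(expr, sets),
                               message = function(m) invokeRestart("muffleMessage")),
    "S3")
  expect_equal(colnames(act), c("S1", "S2"))
  expect_equal(unname(act[, "S2"]),
               unname((expr[, "C"] - mean(expr[, "C"])) / sd(expr[, "C"])))
})

test_that("coherence and global activity are invariant to positive affine transforms", {
  set.seed(10)
  expr <- matrix(rnorm(400), 40, 10,
                 dimnames = list(sprintf("s%d", 1:40), sprintf("g%d", 1:10)))
  sets <- gene_set_collection(list(S1 = sprintf("g%d", 1:4),
                                   S2 = sprintf("g%d", 5:10)), "signature")
  a <- runif(10, 0.5, 3); b <- rnorm(10)
  expr2 <- sweep(sweep(expr, 2, a, `*`), 2, b, `+`)
  for (s in sets$sets)
    expect_equal(coherence_score(t(expr2[, s])), coherence_score(t(expr[, s])),
                 tolerance = 1e-9)
  expect_equal(signature_activity(expr2, sets), signature_activity(expr, sets),
               tolerance = 1e-9)
})

test_that("permuting sample order permutes activity rows identically", {
  set.seed(11)
  expr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("s%d", 1:20), sprintf("g%d", 1:10)))
  sets <- gene_set_collection(list(S = sprintf("g%d", 1:5)), "signature")
  perm <- sample(rownames(expr))
  expect_equal(signature_activity(expr[perm, ], sets),
               signature_activity(expr, sets)[perm, , drop = FALSE])
})

test_that("filtering retains exactly the signatures at or above threshold", {
  b <- small_bundle(seed = 15)
  sc <- score_signatures(b$data$expression, b$signatures, threshold = 0.1)
  expect_true(all(sc$cs[sc$retained] >= 0.1))
  expect_identical(colnames(sc$activity), sc$retained)
  all_in <- filter_signatures(sc, -1)
  expect_setequal(all_in$retained, names(sc$cs)[!is.na(sc$cs)])
  none <- filter_signatures(sc, 1 + 1e-9)
  expect_length(none$retained, 0)
  expect_equal(ncol(none$activity), 0)
})

test_that("train-only scope uses training statistics, not global ones", {
  set.seed(12)
  expr <- matrix(rnorm(300), 30, 10,
                 dimnames = list(sprintf("s%d", 1:30), sprintf("g%d", 1:10)))
  sets <- gene_set_collection(list(S = c("g1", "g2")), "signature")
  train <- sprintf("s%d", 1:20)
  act <- signature_activity(expr, sets, scope = "train_only",
                            train_samples = train)
  mu <- colMeans(expr[train, c("g1", "g2")])
  sds <- apply(expr[train, c("g1", "g2")], 2, sd)
  manual <- rowMeans(sweep(sweep(expr[, c("g1", "g2")], 2, mu), 2, sds, `/`))
  expect_equal(unname(act[, "S"]), unname(manual), tolerance = 1e-12)
  expect_error(signature_activity(expr, sets, scope = "train_only"),
               "train_samples")
})
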