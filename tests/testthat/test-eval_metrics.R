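test_that("feature matrices are well-formed in both modes", {
  M <- build_feature_matrix("AAAA", mode = "position_freq")
  expect_equal(dim(M), c(4L, 4L))
  expect_true(all(M["A", ] == 1))
  expect_equal(colSums(M), rep(1, 4), ignore_attr = TRUE)

  K <- build_feature_matrix("ACGT", mode = "kmer_freq", k = 1)
  expect_equal(as.vector(K), rep(0.25, 4))
  K3 <- build_feature_matrix(c("ACGTACGT", "TTTTTTTT"), mode = "kmer_freq", k = 3)
  expect_equal(sum(K3), 1)
  expect_equal(nrow(K3), 64L)
  expect_error(build_feature_matrix(c("AC", "ACG"), "position_freq"), "equal-length")
})

test_that("pearson matches a textbook computation and its invariances", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), -c(1, 2, 3)), -1)
  # direct formula oracle for (1,2,3,4) vs (1,2,3,5)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), num / den)
  # invariance to positive affine transforms
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson(2 * a + 3, b), pearson(a, b))
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("mae, prd and rmse match elementwise oracles", {
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(mae(x, x), 0)
  expect_equal(mae(x, x + 3), 3)
  expect_equal(mae(x, y), sum(abs(x - y)) / 50)
  expect_equal(prd(x, x), 0)
  expect_equal(prd(x, rep(0, 50)), 100)
  expect_equal(prd(x, y), 100 * sqrt(sum((x - y)^2) / sum(x^2)))
  expect_error(prd(rep(0, 3), 1:3), "all zero")
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 2), 2)
  expect_equal(rmse(x, y), sqrt(mean((x - y)^2)))
})

test_that("mirror column association averages per-column correlations", {
  set.seed(3)
  A <- matrix(rnorm(40), 8, 5)
  expect_equal(as.numeric(mirror_column_association(A, A)), 1)
  B <- matrix(rnorm(40), 8, 5)
  want <- mean(vapply(1:5, function(j) cor(A[, j], B[, j]), numeric(1)))
  expect_equal(as.numeric(mirror_column_association(A, B)), want)
  # single column reduces to pearson
  expect_equal(as.numeric(mirror_column_association(A[, 1, drop = FALSE],
                                                    B[, 1, drop = FALSE])),
               pearson(A[, 1], B[, 1]))
  # zero-variance columns are skipped and counted
  A2 <- A; A2[, 2] <- 1
  r <- mirror_column_association(A2, B)
  expect_identical(attr(r, "n_skipped"), 1L)
  expect_error(mirror_column_association(matrix(1, 4, 2), matrix(1, 4, 2)),
               "zero variance")
})

test_that("frechet distance equals the recursive definition on short curves", {
  expect_equal(frechet_distance(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(frechet_distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  set.seed(4)
  for (i in 1:60) {
    n <- sample(1:8, 1); m <- sample(1:8, 1); d <- sample(1:3, 1)
    O <- matrix(rnorm(n * d), n, d)
    P <- matrix(rnorm(m * d), m, d)
    expect_equal(frechet_distance(O, P), recursive_frechet(O, P),
                 tolerance = 1e-12)
  }
})

test_that("frechet distance dominates the start-point distance", {
  set.seed(5)
  for (i in 1:20) {
    O <- matrix(rnorm(12), 6, 2); P <- matrix(rnorm(12), 6, 2)
    expect_gte(frechet_distance(O, P) + 1e-12, sqrt(sum((O[1, ] - P[1, ])^2)))
  }
})

test_that("classifier metrics match their formulas and edge conventions", {
  perfect <- classifier_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(perfect, c(Acc = 100, MCC = 1, Sen = 100, Spc = 100))
  wrong <- classifier_metrics(list(TP = 0, TN = 0, FP = 10, FN = 10))
  expect_equal(wrong, c(Acc = 0, MCC = -1, Sen = 0, Spc = 0))
  # a zero factor in the MCC denominator (here TP + FP = 0) is defined as 0
  m <- classifier_metrics(list(TP = 0, TN = 5, FP = 0, FN = 5))
  expect_equal(m[["MCC"]], 0)
  expect_error(classifier_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0)),
               "sensitivity")
  expect_error(classifier_metrics(list(TP = 5, TN = 0, FP = 0, FN = 5)),
               "specificity")
})

test_that("confusion counts and metrics agree with a counting oracle", {
  set.seed(6)
  for (i in 1:40) {
    truth <- runif(60) < 0.5
    pred <- runif(60) < 0.5
    if (!any(truth) || all(truth) || !any(pred) || all(pred)) next
    cc <- confusion_counts(truth, pred)
    want <- counting_metrics(truth, pred)
    expect_identical(cc$TP, want$TP)
    expect_identical(cc$TN, want$TN)
    expect_identical(cc$FP, want$FP)
    expect_identical(cc$FN, want$FN)
    total <- with(want, TP + TN + FP + FN)
    expect_equal(classifier_metrics(cc)[["Acc"]],
                 100 * (want$TP + want$TN) / total)
  }
})

test_that("roc_curve handles separation, symmetry and chance", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(sep$auc, 1)
  rev <- roc_curve(-c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(rev$auc, 1 - sep$auc)
  set.seed(7)
  rnd <- roc_curve(rnorm(10000), runif(10000) < 0.5)
  expect_lt(abs(rnd$auc - 0.5), 0.03)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("roc_curve agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(300)
  labels <- runif(300) < plogis(scores)
  if (!any(labels) || all(labels)) skip("degenerate draw")
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("comparing a dataset against itself gives the identity report", {
  sim <- simulate_dataset(50, 30, seed = 9)
  r <- compare_datasets(sim$sequences, sim$sequences)
  expect_equal(r$pearson, 1)
  expect_equal(r$mae, 0)
  expect_equal(r$prd, 0)
  expect_equal(r$rmse, 0)
  expect_equal(r$mirror_column_association, 1)
  expect_equal(r$frechet, 0)
})

test_that("disjoint compositions produce the hand-computable extreme report", {
  allA <- rep(strrep("A", 10), 5)
  allT <- rep(strrep("T", 10), 5)
  r <- compare_datasets(allA, allT)
  # frequency matrices are constant indicators: MAE = 2 * L / (4 * L)
  expect_equal(r$mae, 0.5)
  expect_gt(r$prd, 0)
  # every column pairs the constant profiles (1,0,0,0) vs (0,1,0,0), whose
  # correlation is -1/3: maximal disagreement shows up as a low association
  expect_equal(r$mirror_column_association, -1 / 3)
  expect_equal(r$frechet, sqrt(2))
  # all fields finite or NA on random inputs
  s1 <- simulate_dataset(20, 15, seed = 10)$sequences
  s2 <- simulate_dataset(20, 15, seed = 11)$sequences
  r2 <- compare_datasets(s1, s2, mode = "kmer_freq", k = 2)
  expect_true(all(vapply(r2[c("pearson", "mae", "prd", "rmse", "frechet")],
                         is.finite, logical(1))))
})
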