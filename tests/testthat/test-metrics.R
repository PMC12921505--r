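test_that("confusion counts with pathogenic as positive class", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0L)
  allpos <- confusion(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(allpos$TP, 2L)
  expect_equal(allpos$FP, 2L)
  cc2 <- confusion(c("pathogenic", "benign"), c("pathogenic", "pathogenic"))
  expect_equal(cc2$FP, 1L)
  expect_error(confusion(c(1, 2), c(1, 0)), "NonBinary")
  expect_error(confusion(c(1, 0), c(1)), "LengthMismatch")
})

test_that("MCC and F1 match hand-derived values and conventions", {
  cc <- structure(list(TP = 2L, FP = 1L, TN = 2L, FN = 1L),
                  class = "confusion_counts")
  expect_equal(mcc(cc), 1 / 3)
  expect_equal(f1(cc), 2 / 3, tolerance = 1e-12)
  perfect <- structure(list(TP = 3L, FP = 0L, TN = 4L, FN = 0L),
                       class = "confusion_counts")
  expect_equal(mcc(perfect), 1)
  expect_equal(f1(perfect), 1)
  onesided <- structure(list(TP = 3L, FP = 4L, TN = 0L, FN = 0L),
                        class = "confusion_counts")
  expect_equal(mcc(onesided), 0)   # zero-denominator convention
  empty <- structure(list(TP = 0L, FP = 2L, TN = 0L, FN = 3L),
                     class = "confusion_counts")
  expect_equal(f1(empty), 0)
})

test_that("metrics agree with naive recomputation on random calls", {
  set.seed(404)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5); p <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    cc <- confusion(y, p)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
    num <- cc$TP * cc$TN - cc$FP * cc$FN
    den <- sqrt(prod(c(cc$TP + cc$FP, cc$TP + cc$FN,
                       cc$TN + cc$FP, cc$TN + cc$FN)))
    expect_equal(mcc(cc), if (den == 0) 0 else num / den)
  }
})

test_that("ROC handles separation, ties, and the 4-point fixture", {
  expect_equal(roc_and_auc(c(5, 4, 1, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_and_auc(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  # orientation flip is a mirror image
  expect_equal(roc_and_auc(-c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0),
                           "lower_is_pathogenic")$auc, 0.75)
  r <- roc_and_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
  expect_error(roc_and_auc(1:3, c(1, 1, 1)), "SingleClass")
})

test_that("AUC equals pairwise concordance on random instances", {
  set.seed(77)
  for (i in 1:500) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    orient <- sample(c("lower_is_pathogenic", "higher_is_pathogenic"), 1)
    expect_equal(roc_and_auc(s, y, orient)$auc, oracle_auc(s, y, orient),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  s <- rnorm(40); y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
  a <- roc_and_auc(s, y, "higher_is_pathogenic")$auc
  expect_equal(roc_and_auc(exp(s), y, "higher_is_pathogenic")$auc, a)
  expect_equal(roc_and_auc(-exp(s), y, "lower_is_pathogenic")$auc, a)
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:20) {
    s <- rnorm(50); y <- c(0, 1, rbinom(48, 1, 0.5))
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_and_auc(s, y, "higher_is_pathogenic")$auc, ref,
                 tolerance = 1e-9)
  }
})

test_that("the Youden-optimal threshold maximizes TPR - FPR", {
  # separable case: the returned value attains J = 1 under the classify rule
  s <- c(-1.0, -0.8, -0.2, -0.1); y <- c(1, 1, 0, 0)
  t <- optimal_threshold(s, y, "lower_is_pathogenic")
  calls <- classify(s, threshold = t, orientation = "lower_is_pathogenic")
  expect_equal(calls, c("pathogenic", "pathogenic", "benign", "benign"))
  # randomized equivalence with exhaustive brute force over all cuts
  set.seed(31)
  for (i in 1:500) {
    n <- sample(6:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))
    orient <- sample(c("lower_is_pathogenic", "higher_is_pathogenic"), 1)
    t <- optimal_threshold(s, y, orient)
    calls <- classify(s, threshold = t, orientation = orient)
    j_got <- sum(calls == "pathogenic" & y == 1) / sum(y == 1) -
      sum(calls == "pathogenic" & y == 0) / sum(y == 0)
    expect_equal(j_got, oracle_best_j(s, y, orient), tolerance = 1e-12)
  }
})

test_that("evaluate_scores assembles a coherent report", {
  set.seed(2)
  s <- c(rnorm(30, -2), rnorm(30, 0))       # pathogenic lower
  y <- rep(c(1, 0), each = 30)
  rep <- evaluate_scores(s, y, orientation = "lower_is_pathogenic")
  expect_gt(rep$auc, 0.8)
  expect_gt(rep$mcc, 0.4)
  expect_equal(dim(rep$confusion_percent), c(2L, 2L))
  expect_equal(rowSums(rep$confusion_percent), c(benign = 100, pathogenic = 100))
})
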