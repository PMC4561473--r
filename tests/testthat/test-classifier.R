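ref_fixture <- function(n_probes = 20, n1 = 6, n2 = 6, offset = 5,
                        seed = 1) {
  em <- make_separated_em(n_probes, n1, n2, offset = offset, seed = seed)
  st <- make_samples(sample_ids(em), rep(c("young", "old"), c(n1, n2)),
                     levels = c("young", "old"))
  sig <- signature_model(probe_ids(em), "up", 0.95)
  list(em = em, st = st, sig = sig)
}

test_that("a test sample identical to a reference sample is its own neighbour", {
  f <- ref_fixture()
  test_vals <- f$em$exprs[, "s10", drop = FALSE]
  colnames(test_vals) <- "t1"
  test_em <- expression_matrix(test_vals)
  res <- knn_classify_external(f$em, f$st, test_em, f$sig, k = 1)
  expect_equal(res$predicted_label, "old")
  expect_equal(res$vote_score, 1)
})

test_that("well-separated clusters classify perfectly and match the kNN oracle", {
  f <- ref_fixture(offset = 2, seed = 2)
  set.seed(3)
  test_vals <- matrix(rnorm(20 * 20), 20)
  test_vals[, 11:20] <- test_vals[, 11:20] + 2
  test_em <- make_em(test_vals, probes = probe_ids(f$em),
                     samples = paste0("t", 1:20))
  truth <- make_samples(sample_ids(test_em),
                        rep(c("young", "old"), each = 10),
                        levels = c("young", "old"))
  res <- knn_classify_external(f$em, f$st, test_em, f$sig, k = 5,
                               test_labels = truth)
  expect_equal(res$predicted_label, res$true_label)  # 100 % at 2 sd

  # predictions equal an exhaustive distance-search oracle
  mu <- rowMeans(f$em$exprs); sdv <- apply(f$em$exprs, 1, sd)
  ztrain <- (f$em$exprs - mu) / sdv
  is_case <- rep(c(FALSE, TRUE), c(6, 6))
  for (s in seq_len(20)) {
    pred <- oracle_knn_predict(ztrain, is_case,
                               (test_em$exprs[, s] - mu) / sdv, 5)
    expect_equal(res$predicted_label[s], if (pred) "old" else "young")
  }
})

test_that("external classification guards its preconditions", {
  f <- ref_fixture()
  test_em <- make_em(matrix(rnorm(20), 20, 1), probes = probe_ids(f$em))
  sig_absent <- signature_model(paste0("zz", 1:10), "up", 0.9)
  expect_error(knn_classify_external(f$em, f$st, test_em, sig_absent),
               "no signature probes")
  sig_half <- signature_model(c(probe_ids(f$em)[1:4], paste0("zz", 1:6)),
                              "up", 0.9)
  expect_error(knn_classify_external(f$em, f$st, test_em, sig_half),
               "< 50%")
  expect_error(knn_classify_external(f$em, f$st, test_em, f$sig, k = 13),
               "exceeds")
  expect_warning(knn_classify_external(f$em, f$st, test_em, f$sig, k = 2),
                 "even k")
})

test_that("LOOCV classification is exact on separated data and order-invariant", {
  f <- ref_fixture(n_probes = 10, n1 = 3, n2 = 3, offset = 6, seed = 4)
  res <- knn_classify_loocv(f$em, f$st, f$sig, k = 1)
  expect_equal(res$predicted_label, res$true_label)   # 6/6 correct

  f2 <- ref_fixture(n_probes = 15, n1 = 8, n2 = 8, offset = 1.5, seed = 5)
  r1 <- knn_classify_loocv(f2$em, f2$st, f2$sig, k = 5)
  perm <- c(9:16, 1:8)
  em_perm <- expression_matrix(f2$em$exprs[, perm])
  r2 <- knn_classify_loocv(em_perm, f2$st, f2$sig, k = 5)
  expect_equal(r1[order(r1$sample_id), ], r2[order(r2$sample_id), ],
               ignore_attr = TRUE)
})

test_that("LOOCV accuracy sits at chance on label-permuted null data", {
  set.seed(6)
  em <- make_em(matrix(rnorm(15 * 20), 15, 20))
  labels <- sample(rep(c("young", "old"), each = 10))
  st <- make_samples(sample_ids(em), labels, levels = c("young", "old"))
  sig <- signature_model(probe_ids(em), "up", 0.9)
  res <- knn_classify_loocv(em, st, sig, k = 5)
  acc <- mean(res$predicted_label == res$true_label)
  band <- qnorm(0.995) * sqrt(0.25 / 20)
  expect_lt(abs(acc - 0.5), band + 0.1)   # slack for hold-out imbalance
})

test_that("AUC follows the rank formula, oracle and symmetry", {
  mk <- function(scores, pos) {
    structure(data.frame(sample_id = seq_along(scores),
                         predicted_label = "x", vote_score = scores,
                         true_label = ifelse(pos, "old", "young")),
              class = c("ClassificationResult", "data.frame"),
              groups = c("young", "old"), k = 5)
  }
  expect_equal(roc_auc(mk(c(0.9, 0.8, 0.2, 0.1),
                          c(TRUE, TRUE, FALSE, FALSE)))$auc, 1.0)
  expect_equal(roc_auc(mk(c(1, 3, 2, 4),
                          c(TRUE, TRUE, FALSE, FALSE)))$auc, 0.25)
  expect_equal(roc_auc(mk(rep(0.4, 6), rep(c(TRUE, FALSE), 3)))$auc, 0.5)

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) next
    r <- mk(scores, pos)
    expect_equal(roc_auc(r)$auc, oracle_auc(scores, pos))
    neg <- r; neg$vote_score <- -neg$vote_score
    expect_equal(roc_auc(neg)$auc, 1 - roc_auc(r)$auc)
  }
})

test_that("AUC matches the pROC cross-check on untied scores", {
  set.seed(8)
  scores <- rnorm(60)
  pos <- rep(c(TRUE, FALSE), 30)
  r <- structure(data.frame(sample_id = 1:60, predicted_label = "x",
                            vote_score = scores,
                            true_label = ifelse(pos, "old", "young")),
                 class = c("ClassificationResult", "data.frame"),
                 groups = c("young", "old"))
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = scores, direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(r)$auc, proc_auc)
})

test_that("the ROC curve is monotone and anchored", {
  set.seed(9)
  r <- structure(data.frame(sample_id = 1:30, predicted_label = "x",
                            vote_score = sample(seq(0, 1, 0.2), 30, TRUE),
                            true_label = sample(c("old", "young"), 30,
                                                TRUE)),
                 class = c("ClassificationResult", "data.frame"),
                 groups = c("young", "old"))
  curve <- roc_auc(r)$curve
  expect_false(is.unsorted(rev(curve$sensitivity)))
  expect_false(is.unsorted(curve$specificity))
  expect_equal(curve$sensitivity[1], 1)
  expect_equal(curve$specificity[1], 0)
})

test_that("confusion metrics match their definitions", {
  mk <- function(pred, true) {
    structure(data.frame(sample_id = seq_along(pred),
                         predicted_label = pred, vote_score = 0.5,
                         true_label = true),
              class = c("ClassificationResult", "data.frame"),
              groups = c("young", "old"))
  }
  m <- confusion_metrics(mk(
    pred = c("old", "old", "old", "young", rep("young", 4)),
    true = c(rep("old", 4), rep("young", 4))))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 7 / 8)

  # no positives: sensitivity is absent, not zero
  m0 <- confusion_metrics(mk(pred = c("young", "old"),
                             true = c("young", "young")))
  expect_true(is.na(m0$sensitivity))
  expect_equal(m0$specificity, 0.5)

  # random confusion tables against the (TP + TN) / n definition
  set.seed(10)
  for (rep in 1:20) {
    pred <- sample(c("old", "young"), 30, TRUE)
    true <- sample(c("old", "young"), 30, TRUE)
    m <- confusion_metrics(mk(pred, true))
    expect_equal(m$accuracy, mean(pred == true))
  }
})
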