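#' Classify unknown samples against a reference expression space
#'
#' External validation in the strict sense: a cohort of "known samples"
#' defines the feature space (the signature probes) and its scaling, and
#' every test sample is classified independently by a k-nearest-neighbour
#' majority vote among the reference samples. The reference set is never
#' re-fit per test sample. Features are z-scored per probe using reference
#' mean and standard deviation; this is a deliberate, documented
#' simplification of cross-study frozen normalization.
#'
#' @param reference An [expression_matrix()] of known samples.
#' @param reference_labels A [sample_table()] for the reference samples.
#' @param test An [expression_matrix()] of unknown samples.
#' @param signature A [signature_model()]; probes present in both matrices
#'   are used. Fewer than 50 percent of signature probes present is an
#'   error.
#' @param k Neighbours (default 5). Even `k` draws a warning; vote ties
#'   resolve to the nearest neighbour's label.
#' @param groups Length-2 `(reference_level, case_level)` vector, e.g.
#'   `c("young", "old")`; `vote_score` is the fraction of neighbours with
#'   the case label. Defaults to the factor levels.
#' @param test_labels Optional [sample_table()] for the test samples; when
#'   supplied, true labels are attached for downstream ROC analysis.
#' @return A data frame of class `ClassificationResult` with columns
#'   `sample_id`, `predicted_label`, `vote_score` and (optionally)
#'   `true_label`; attributes `k` and `groups`.
#' @export
knn_classify_external <- function(reference, reference_labels, test,
                                  signature, k = 5, groups = NULL,
                                  test_labels = NULL) {
  stopifnot(inherits(reference, "ExpressionMatrix"),
            inherits(reference_labels, "SampleTable"),
            inherits(test, "ExpressionMatrix"),
            inherits(signature, "SignatureModel"))
  feats <- intersect(signature$probe_id,
                     intersect(probe_ids(reference), probe_ids(test)))
  if (length(feats) == 0)
    stop("no signature probes shared by reference and test matrices",
         call. = FALSE)
  if (length(feats) < 0.5 * nrow(signature))
    stop("only ", length(feats), " of ", nrow(signature),
         " signature probes present (< 50%)", call. = FALSE)
  if (k > ncol(reference$exprs))
    stop("k exceeds the number of reference samples", call. = FALSE)
  if (k %% 2 == 0)
    warning("even k = ", k, ": binary vote ties resolve to the nearest ",
            "neighbour's label", call. = FALSE)
  if (is.null(groups)) groups <- levels(reference_labels$group)
  if (length(groups) != 2)
    stop("exactly two group labels are required", call. = FALSE)
  ref <- reference$exprs[feats, , drop = FALSE]
  lab <- as.character(reference_labels$group[
    match(colnames(ref), reference_labels$sample_id)])
  if (anyNA(lab))
    stop("reference sample(s) missing from the sample table", call. = FALSE)
  mu <- rowMeans(ref)
  sdv <- apply(ref, 1, stats::sd)
  sdv[sdv == 0] <- 1
  zref <- (ref - mu) / sdv
  is_case <- lab == groups[2]
  tst <- (test$exprs[feats, , drop = FALSE] - mu) / sdv
  res <- lapply(seq_len(ncol(tst)),
                function(s) knn_vote(tst[, s], zref, is_case, k))
  finish_classification(colnames(tst), res, groups, k, test_labels)
}

#' Within-cohort leave-one-out kNN classification
#'
#' Each sample is classified against all the others; the per-probe z-score
#' scaling is re-estimated from the `n - 1` retained samples at every fold,
#' so the held-out sample never influences its own feature scaling.
#'
#' @inheritParams knn_classify_external
#' @param matrix An [expression_matrix()].
#' @param labels A [sample_table()] covering its samples.
#' @return A `ClassificationResult` (see [knn_classify_external()]) with
#'   `true_label` always present.
#' @export
knn_classify_loocv <- function(matrix, labels, signature, k = 5,
                               groups = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(labels, "SampleTable"),
            inherits(signature, "SignatureModel"))
  feats <- intersect(signature$probe_id, probe_ids(matrix))
  if (length(feats) == 0)
    stop("no signature probes present in the matrix", call. = FALSE)
  if (length(feats) < 0.5 * nrow(signature))
    stop("only ", length(feats), " of ", nrow(signature),
         " signature probes present (< 50%)", call. = FALSE)
  if (is.null(groups)) groups <- levels(labels$group)
  if (length(groups) != 2)
    stop("exactly two group labels are required", call. = FALSE)
  if (k %% 2 == 0)
    warning("even k = ", k, ": binary vote ties resolve to the nearest ",
            "neighbour's label", call. = FALSE)
  x <- matrix$exprs[feats, , drop = FALSE]
  lab <- as.character(labels$group[match(colnames(x), labels$sample_id)])
  if (anyNA(lab))
    stop("sample(s) missing from the sample table", call. = FALSE)
  for (g in groups)
    if (sum(lab == g) < k + 1)
      stop("group '", g, "' has fewer than k + 1 = ", k + 1, " samples",
           call. = FALSE)
  is_case <- lab == groups[2]
  n <- ncol(x)
  res <- lapply(seq_len(n), function(s) {
    keep <- setdiff(seq_len(n), s)
    train <- x[, keep, drop = FALSE]
    mu <- rowMeans(train)
    sdv <- apply(train, 1, stats::sd)
    sdv[sdv == 0] <- 1
    knn_vote((x[, s] - mu) / sdv, (train - mu) / sdv, is_case[keep], k)
  })
  out <- finish_classification(colnames(x), res, groups, k, NULL)
  out$true_label <- lab
  out
}

finish_classification <- function(sample_id, votes, groups, k,
                                  test_labels) {
  out <- data.frame(
    sample_id = sample_id,
    predicted_label = ifelse(vapply(votes, `[[`, logical(1), "is_case"),
                             groups[2], groups[1]),
    vote_score = vapply(votes, `[[`, numeric(1), "vote"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(test_labels)) {
    out$true_label <- as.character(
      test_labels$group[match(out$sample_id, test_labels$sample_id)])
  }
  attr(out, "k") <- k
  attr(out, "groups") <- groups
  class(out) <- c("ClassificationResult", "data.frame")
  out
}

#' ROC curve and AUC for a classification result
#'
#' The ranking variable is `vote_score` (fraction of case-labelled
#' neighbours). The AUC is computed by the rank formula
#' \eqn{AUC = U / (n_{pos} n_{neg})}, the Mann-Whitney U of the case
#' scores, with ties contributing one half — identical to the probability
#' that a random case outscores a random control.
#'
#' @param result A `ClassificationResult` with `true_label` present, or any
#'   data frame with `vote_score` and `true_label` columns.
#' @param case_label The positive class; defaults to the second entry of
#'   the result's `groups` attribute.
#' @return A list of class `RocCurve`: `curve` (data frame of `threshold`,
#'   `sensitivity`, `specificity`) and `auc`.
#' @export
roc_auc <- function(result, case_label = NULL) {
  if (is.null(case_label)) case_label <- attr(result, "groups")[2]
  if (is.null(result$true_label))
    stop("true labels are required for ROC analysis", call. = FALSE)
  pos <- result$true_label == case_label
  if (all(pos) || !any(pos))
    stop("ROC needs both classes present", call. = FALSE)
  scores <- result$vote_score
  r <- rank(scores)                       # average ranks handle ties
  n_pos <- sum(pos); n_neg <- sum(!pos)
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  thr <- sort(unique(scores))
  curve <- data.frame(
    threshold = c(-Inf, thr),
    sensitivity = vapply(c(-Inf, thr),
                         function(t) mean(scores[pos] > t), numeric(1)),
    specificity = vapply(c(-Inf, thr),
                         function(t) mean(scores[!pos] <= t), numeric(1)))
  structure(list(curve = curve, auc = auc,
                 n_pos = n_pos, n_neg = n_neg), class = "RocCurve")
}

#' @export
print.RocCurve <- function(x, ...) {
  cat(sprintf("RocCurve: AUC = %.4f (%d cases vs %d controls)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a classification result
#'
#' @inheritParams roc_auc
#' @return A list with `sensitivity`, `specificity`, `accuracy` and the
#'   2x2 counts. A ratio with an empty denominator (e.g. sensitivity with
#'   no positives) is reported as `NA`, never as 0.
#' @export
confusion_metrics <- function(result, case_label = NULL) {
  if (is.null(case_label)) case_label <- attr(result, "groups")[2]
  if (is.null(result$true_label))
    stop("true labels are required", call. = FALSE)
  pos <- result$true_label == case_label
  pred_pos <- result$predicted_label == case_label
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy = ratio(tp + tn, tp + fn + tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}
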