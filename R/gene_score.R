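#' Direction-aware median-rank gene score
#'
#' The healthy-ageing gene score. For each signature gene present in the
#' matrix, samples are ranked within the cohort: for a gene down-regulated
#' with age the highest-expressing sample gets rank 1 and the lowest rank
#' `n`; for an up-regulated gene the opposite. Ties receive average ranks.
#' Each sample's raw score is the median (or, behind a flag, the sum) of
#' its per-gene ranks — the median ensures every gene carries equal
#' weight — and the scaled score divides by `n` so that cohorts of
#' different sizes plot on a common `(0, 1]` axis. Higher scores mean a
#' profile more like healthy older tissue. Scores are cohort-relative by
#' construction: adding or removing samples changes every score.
#'
#' @param matrix An [expression_matrix()] for the cohort to be scored.
#' @param signature A [signature_model()]. Signature probes absent from
#'   the matrix are skipped with a message.
#' @param method `"median"` (default) or `"sum"` aggregation across genes.
#' @return A data frame of class `GeneScoreResult` with columns
#'   `sample_id`, `raw_score`, `scaled_score` (`raw_score / n` for the
#'   median method, `raw_score / (n * n_genes)` for the sum method) and
#'   attribute `n_genes_used`.
#' @export
compute_gene_score <- function(matrix, signature,
                               method = c("median", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(signature, "SignatureModel"))
  n <- ncol(matrix$exprs)
  if (n < 2) stop("at least 2 samples are required", call. = FALSE)
  present <- signature$probe_id %in% probe_ids(matrix)
  if (!any(present))
    stop("no signature genes present in the matrix", call. = FALSE)
  if (any(!present))
    message(sum(!present), " signature gene(s) absent from the matrix; ",
            "skipped")
  sig <- signature[present, , drop = FALSE]
  ranks <- vapply(seq_len(nrow(sig)), function(i) {
    x <- matrix$exprs[sig$probe_id[i], ]
    if (sig$direction[i] == "down") rank(-x, ties.method = "average")
    else rank(x, ties.method = "average")
  }, numeric(n))                       # n x n_genes
  raw <- if (method == "median") apply(ranks, 1, stats::median)
         else rowSums(ranks)
  scaled <- if (method == "median") raw / n else raw / (n * ncol(ranks))
  out <- data.frame(sample_id = sample_ids(matrix), raw_score = raw,
                    scaled_score = scaled, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n_genes_used") <- nrow(sig)
  attr(out, "method") <- method
  class(out) <- c("GeneScoreResult", "data.frame")
  out
}

scores_by_group <- function(scores, labels) {
  stopifnot(inherits(scores, "GeneScoreResult"),
            inherits(labels, "SampleTable"))
  grp <- labels$group[match(scores$sample_id, labels$sample_id)]
  if (anyNA(grp))
    stop("scored sample(s) missing from the sample table", call. = FALSE)
  split(scores$scaled_score, grp, drop = TRUE)
}

#' Two-group comparison of gene scores (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test on the scaled scores; exact distribution for
#' small tie-free samples (combined n of 20 or fewer), normal
#' approximation with tie correction otherwise — the default behaviour of
#' [stats::wilcox.test()].
#'
#' @param scores A [compute_gene_score()] result.
#' @param labels A [sample_table()] covering the scored samples.
#' @param group_a,group_b The two group labels to compare.
#' @return A list of class `GroupComparison`: `statistic` (Mann-Whitney
#'   U of `group_a`), `p_value` and the two `group_medians`.
#' @export
wilcoxon_compare <- function(scores, labels, group_a, group_b) {
  by_grp <- scores_by_group(scores, labels)
  for (g in c(group_a, group_b))
    if (!g %in% names(by_grp) || length(by_grp[[g]]) == 0)
      stop("group '", g, "' is empty or unknown", call. = FALSE)
  a <- by_grp[[group_a]]; b <- by_grp[[group_b]]
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 group_medians = stats::setNames(
                   c(stats::median(a), stats::median(b)),
                   c(group_a, group_b))),
            class = "GroupComparison")
}

#' Kruskal-Wallis test across score groups
#'
#' Used when comparing more than two groups with unequal sizes (e.g. the
#' gene score across brain regions or age strata): H statistic with tie
#' correction and a chi-square p-value on `g - 1` degrees of freedom, via
#' [stats::kruskal.test()].
#'
#' @inheritParams wilcoxon_compare
#' @return A `GroupComparison` with `statistic` (H), `df`, `p_value` and
#'   per-group medians.
#' @export
kruskal_wallis <- function(scores, labels) {
  by_grp <- scores_by_group(scores, labels)
  if (length(by_grp) < 2)
    stop("at least 2 non-empty groups are required", call. = FALSE)
  kt <- stats::kruskal.test(by_grp)
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value,
                 group_medians = vapply(by_grp, stats::median, numeric(1))),
            class = "GroupComparison")
}

#' Post hoc pairwise Mann-Whitney tests with Holm correction
#'
#' All pairwise two-sided rank-sum tests between score groups, with the
#' Holm step-down adjustment (monotone, capped at 1) applied across the
#' family.
#'
#' @inheritParams wilcoxon_compare
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `statistic`, `p_value`, `adjusted_p`.
#' @export
posthoc_mw_holm <- function(scores, labels) {
  by_grp <- scores_by_group(scores, labels)
  if (length(by_grp) < 2)
    stop("at least 2 non-empty groups are required", call. = FALSE)
  pairs <- utils::combn(names(by_grp), 2)
  res <- apply(pairs, 2, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(by_grp[[pr[1]]],
                                              by_grp[[pr[2]]]))
    c(statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    statistic = res["statistic", ],
                    p_value = res["p_value", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Linear regression of the gene score on a clinical covariate
#'
#' Ordinary least squares of scaled score on one covariate, reporting the
#' slope, intercept, r-squared and the slope's t-test p-value.
#'
#' @param scores A [compute_gene_score()] result.
#' @param covariate Numeric vector, one value per scored sample (same
#'   order), or a named vector matched by sample id.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_score <- function(scores, covariate) {
  stopifnot(inherits(scores, "GeneScoreResult"))
  if (!is.null(names(covariate)))
    covariate <- covariate[scores$sample_id]
  if (length(covariate) != nrow(scores))
    stop("covariate length does not match the number of scored samples",
         call. = FALSE)
  ok <- is.finite(covariate) & is.finite(scores$scaled_score)
  if (sum(ok) < 3)
    stop("at least 3 paired observations are required", call. = FALSE)
  x <- covariate[ok]; y <- scores$scaled_score[ok]
  if (stats::var(x) == 0)
    stop("covariate is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = sum(ok))
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison: statistic = %.4g, p = %.4g\n",
              x$statistic, x$p_value))
  cat("group medians:",
      paste(sprintf("%s = %.4g", names(x$group_medians), x$group_medians),
            collapse = ", "), "\n")
  invisible(x)
}
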