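#' Selection configuration
#'
#' Tuning parameters for the nested hold-out selection loop.
#'
#' @param n_inner Probes entering the feature space at each inner selection
#'   (default 200).
#' @param k Neighbours for the kNN vote (default 5; odd values avoid
#'   binary vote ties).
#' @param perf_threshold Minimum per-probe performance for the final
#'   signature (default 0.90).
#' @param relaxed_threshold Threshold for the secondary, extended list
#'   (default 0.70).
#' @param top_n Signature size cap (default 150).
#' @param min_appearance_frac Minimum appearances, as a fraction of total
#'   hold-out decisions, below which a probe is ineligible (default 0.10);
#'   this keeps rarely-selected "lucky" probes from reaching the
#'   performance threshold on a handful of decisions.
#' @return A list of class `SelectionConfig`.
#' @export
selection_config <- function(n_inner = 200, k = 5, perf_threshold = 0.90,
                             relaxed_threshold = 0.70, top_n = 150,
                             min_appearance_frac = 0.10) {
  stopifnot(relaxed_threshold > 0, relaxed_threshold <= perf_threshold,
            perf_threshold <= 1, n_inner >= k, k >= 1, top_n >= 1,
            min_appearance_frac >= 0, min_appearance_frac <= 1)
  structure(list(n_inner = as.integer(n_inner), k = as.integer(k),
                 perf_threshold = perf_threshold,
                 relaxed_threshold = relaxed_threshold,
                 top_n = as.integer(top_n),
                 min_appearance_frac = min_appearance_frac),
            class = "SelectionConfig")
}

#' Assemble a performance table from per-probe tallies
#'
#' Mostly useful for reconstructing a table from serialized counts;
#' [nested_loocv_select()] produces these directly.
#'
#' @param probe_id Character vector of probe ids (unique).
#' @param appearances,correct Integer tallies per probe
#'   (`0 <= correct <= appearances`).
#' @param n_decisions Total number of hold-out decisions the tallies came
#'   from.
#' @param n_inner Probes per inner selection.
#' @return A `PerformanceTable` data frame (see [nested_loocv_select()]).
#' @export
performance_table <- function(probe_id, appearances, correct, n_decisions,
                              n_inner = NA_integer_) {
  stopifnot(length(probe_id) == length(appearances),
            length(probe_id) == length(correct),
            !anyDuplicated(probe_id),
            all(correct >= 0), all(correct <= appearances),
            all(appearances <= n_decisions))
  out <- data.frame(probe_id = as.character(probe_id),
                    appearances = as.integer(appearances),
                    correct = as.integer(correct),
                    performance = correct / appearances,
                    decision_share = correct / n_decisions,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$decision_share, -out$appearances), , drop = FALSE]
  attr(out, "n_decisions") <- as.integer(n_decisions)
  attr(out, "n_inner") <- n_inner
  class(out) <- c("PerformanceTable", "data.frame")
  out
}

#' Nested hold-out LOOCV probe selection
#'
#' The double hold-out loop that tallies per-probe classification
#' performance. For every ordered pair of distinct samples `(i, j)` both
#' are removed; moderated t-statistics computed on the remaining `n - 2`
#' samples rank the probes, the top `n_inner` define the feature space, and
#' sample `i` is classified by a k-nearest-neighbour majority vote among
#' the `n - 2` retained samples (Euclidean distance on per-probe z-scores
#' estimated from the retained samples only). The decision's correctness is
#' credited to each of the `n_inner` contributing probes. With `n` samples
#' there are exactly `n * (n - 1)` decisions and
#' `n * (n - 1) * n_inner` probe-evaluation events. The procedure is
#' deterministic given its inputs and invariant to sample ordering.
#'
#' @param matrix An [expression_matrix()].
#' @param samples A [sample_table()] with a two-level group.
#' @param cfg A [selection_config()].
#' @param groups Length-2 character vector `(reference, case)`, e.g.
#'   `c("young", "old")`. Defaults to the factor levels.
#' @return A data frame of class `PerformanceTable` with columns
#'   `probe_id`, `appearances`, `correct`, `performance`
#'   (`correct / appearances`, the accuracy of the decisions the probe
#'   contributed to) and `decision_share` (`correct / n_decisions`, the
#'   share of all hold-out decisions the probe was correctly involved in),
#'   restricted to probes selected at least once. Attributes:
#'   `n_decisions`, `n_inner`, `accuracy` (overall held-out accuracy) and
#'   `decisions` (one row per ordered pair with its outcome).
#' @export
nested_loocv_select <- function(matrix, samples, cfg = selection_config(),
                                groups = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(samples, "SampleTable"),
            inherits(cfg, "SelectionConfig"))
  x <- matrix$exprs
  n <- ncol(x)
  if (nrow(x) < cfg$n_inner)
    stop("matrix has fewer probes (", nrow(x), ") than n_inner (",
         cfg$n_inner, ")", call. = FALSE)
  if (is.null(groups)) groups <- levels(samples$group)
  if (length(groups) != 2)
    stop("exactly two group labels are required", call. = FALSE)
  lab <- as.character(samples$group[match(colnames(x), samples$sample_id)])
  if (anyNA(lab))
    stop("sample(s) missing from the sample table: ",
         paste(utils::head(colnames(x)[is.na(lab)], 5), collapse = ", "),
         call. = FALSE)
  for (g in groups)
    if (sum(lab == g) < cfg$k + 1)
      stop("group '", g, "' has fewer than k + 1 = ", cfg$k + 1, " samples",
           call. = FALSE)
  is_case <- lab == groups[2]

  appearances <- integer(nrow(x))
  correct <- integer(nrow(x))
  dec_i <- integer(0); dec_j <- integer(0); dec_ok <- logical(0)

  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      keep <- setdiff(seq_len(n), c(a, b))
      k1 <- keep[!is_case[keep]]
      k2 <- keep[is_case[keep]]
      st <- pooled_t_stats(x, k1, k2)
      hyp <- estimate_variance_prior(st$s2, st$df)
      s2_tilde <- if (is.infinite(hyp$df_prior)) hyp$var_prior else
        (hyp$df_prior * hyp$var_prior + st$df * st$s2) /
          (hyp$df_prior + st$df)
      mod_t <- st$mean_diff / sqrt(s2_tilde * st$se_factor)
      top <- order(-abs(mod_t))[seq_len(cfg$n_inner)]

      train <- x[top, keep, drop = FALSE]
      mu <- rowMeans(train)
      sdv <- sqrt(rowSums((train - mu)^2) / (length(keep) - 1))
      sdv[sdv == 0] <- 1          # constant feature carries no distance
      ztrain <- (train - mu) / sdv
      train_case <- is_case[keep]

      ok_a <- knn_vote((x[top, a] - mu) / sdv, ztrain, train_case,
                       cfg$k)$is_case == is_case[a]
      ok_b <- knn_vote((x[top, b] - mu) / sdv, ztrain, train_case,
                       cfg$k)$is_case == is_case[b]

      appearances[top] <- appearances[top] + 2L
      correct[top] <- correct[top] + (ok_a + ok_b)
      dec_i <- c(dec_i, a, b); dec_j <- c(dec_j, b, a)
      dec_ok <- c(dec_ok, ok_a, ok_b)
    }
  }

  sel <- appearances > 0
  n_dec <- n * (n - 1L)
  out <- data.frame(probe_id = rownames(x)[sel],
                    appearances = appearances[sel],
                    correct = correct[sel],
                    performance = correct[sel] / appearances[sel],
                    decision_share = correct[sel] / n_dec,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$decision_share, -out$appearances), , drop = FALSE]
  attr(out, "n_decisions") <- n * (n - 1L)
  attr(out, "n_inner") <- cfg$n_inner
  attr(out, "accuracy") <- mean(dec_ok)
  attr(out, "groups") <- groups
  attr(out, "decisions") <- data.frame(
    classified = colnames(x)[dec_i], also_held_out = colnames(x)[dec_j],
    correct = dec_ok, stringsAsFactors = FALSE)
  class(out) <- c("PerformanceTable", "data.frame")
  out
}

# Majority vote of the k nearest training samples (Euclidean, z-scored
# feature space). Distance ties break towards the lowest sample index;
# vote ties (possible for even k) towards the single nearest neighbour.
knn_vote <- function(z, ztrain, train_case, k) {
  d2 <- colSums((ztrain - z)^2)
  nn <- order(d2)[seq_len(k)]
  votes_case <- sum(train_case[nn])
  if (2L * votes_case == k) {
    is_case <- train_case[nn[1]]
  } else {
    is_case <- votes_case > k / 2
  }
  list(is_case = is_case, vote = votes_case / k)
}

#' Build the directional signature from a performance table
#'
#' Multi-locus probe-sets (ambiguous genomic targets) are removed first,
#' then probes whose appearance count falls below
#' `min_appearance_frac * n_decisions`. The quantity thresholded and
#' ranked is the probe's *decision share* — the fraction of all hold-out
#' decisions the probe was correctly involved in ("involved in >90 %
#' correct decisions"). Per-probe accuracy (`correct / appearances`) is a
#' poor ranking key here: when held-out accuracy is high it saturates, so
#' a rarely-selected probe that was lucky on its few appearances outranks
#' a probe selected in every single decision; the decision share rewards
#' exactly the probes that are both stably selected and carried by correct
#' decisions. Survivors at or above `perf_threshold` are ranked by
#' decision share, then appearances, then the absolute moderated t on the
#' full training matrix, and the top `top_n` are retained. Each probe's direction is fixed once, on the full training
#' matrix: `down` if the case (old) group mean is below the reference
#' (young) group mean, `up` otherwise. The extended list of probes at or
#' above `relaxed_threshold` (same filters, no size cap) is attached as
#' attribute `"relaxed"`.
#'
#' @param perf A `PerformanceTable` from [nested_loocv_select()].
#' @param matrix,samples The full training matrix and metadata the table
#'   was computed from.
#' @param annotation A [probe_annotation()] supplying `multi_locus` flags;
#'   probes absent from it are assumed single-locus.
#' @param cfg The [selection_config()] used for selection.
#' @param groups Length-2 `(reference, case)` vector, as in
#'   [nested_loocv_select()].
#' @return A [signature_model()]; fewer than `top_n` survivors yields a
#'   shorter signature with a warning, never padding.
#' @export
build_signature <- function(perf, matrix, samples, annotation,
                            cfg = selection_config(), groups = NULL) {
  stopifnot(inherits(perf, "PerformanceTable"))
  if (nrow(perf) == 0) stop("empty performance table", call. = FALSE)
  if (is.null(groups)) groups <- attr(perf, "groups")
  mt <- moderated_t(matrix, samples, groups = groups)
  tab <- merge(as.data.frame(perf),
               mt[c("probe_id", "mean_diff", "moderated_t")],
               by = "probe_id")
  multi <- annotation$probe_id[annotation$multi_locus]
  tab <- tab[!tab$probe_id %in% multi, , drop = FALSE]
  min_app <- cfg$min_appearance_frac * attr(perf, "n_decisions")
  tab <- tab[tab$appearances >= min_app, , drop = FALSE]
  tab <- tab[order(-tab$decision_share, -tab$appearances,
                   -abs(tab$moderated_t)), , drop = FALSE]
  tab$direction <- ifelse(tab$mean_diff < 0, "down", "up")

  make_model <- function(rows, note) {
    signature_model(rows$probe_id, rows$direction, rows$decision_share,
                    training_note = note)
  }
  relaxed_rows <- tab[tab$decision_share >= cfg$relaxed_threshold, ,
                      drop = FALSE]
  strict_rows <- tab[tab$decision_share >= cfg$perf_threshold, ,
                     drop = FALSE]
  if (nrow(strict_rows) == 0)
    stop("no probes reached the performance threshold ", cfg$perf_threshold,
         call. = FALSE)
  if (nrow(strict_rows) < cfg$top_n)
    warning("only ", nrow(strict_rows), " probes reached performance ",
            cfg$perf_threshold, " (requested top_n = ", cfg$top_n, ")",
            call. = FALSE)
  strict_rows <- utils::head(strict_rows, cfg$top_n)
  sig <- make_model(strict_rows, sprintf(
    "nested LOOCV: %d decisions, perf >= %g, top %d",
    attr(perf, "n_decisions"), cfg$perf_threshold, nrow(strict_rows)))
  attr(sig, "relaxed") <- make_model(relaxed_rows, sprintf(
    "extended list, perf >= %g", cfg$relaxed_threshold))
  sig
}

#' Merge two signature models
#'
#' Union of the entries; on a probe collision the first signature's
#' direction is kept (with a warning if the directions conflict) and the
#' larger performance value is retained. Merging disjoint 150- and
#' 48-probe signatures yields the 198-probe combined classifier.
#'
#' @param a,b [signature_model()] objects.
#' @return A merged [signature_model()].
#' @export
merge_signatures <- function(a, b) {
  stopifnot(inherits(a, "SignatureModel"), inherits(b, "SignatureModel"))
  common <- intersect(a$probe_id, b$probe_id)
  if (length(common)) {
    da <- a$direction[match(common, a$probe_id)]
    db <- b$direction[match(common, b$probe_id)]
    if (any(da != db))
      warning(sum(da != db), " colliding probe(s) with conflicting ",
              "directions; keeping the first signature's direction",
              call. = FALSE)
    pa <- a$performance[match(common, a$probe_id)]
    pb <- b$performance[match(common, b$probe_id)]
    a$performance[match(common, a$probe_id)] <- pmax(pa, pb)
  }
  extra <- b[!b$probe_id %in% a$probe_id, , drop = FALSE]
  signature_model(c(a$probe_id, extra$probe_id),
                  c(a$direction, extra$direction),
                  c(a$performance, extra$performance),
                  training_note = "merged signature")
}
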