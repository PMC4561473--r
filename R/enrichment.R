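#' Hypergeometric over-representation test
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the actual overlap between the query set and the term, drawing
#' `|query|` genes from a universe of `|universe|` of which
#' `|term intersect universe|` are term members. Only over-representation
#' is tested. A term disjoint from the query has p exactly 1
#' (`P(X >= 0)`).
#'
#' @param query Character vector of gene symbols; must be a subset of
#'   `universe`.
#' @param gmt A [gene_set_collection()]; terms are intersected with the
#'   universe before testing.
#' @param universe Character vector: the background population (all genes
#'   on the platform).
#' @return A data frame of class `EnrichmentProfile` with columns
#'   `term_id`, `overlap`, `term_size`, `query_size`, `p_value`,
#'   `bh_adjusted_p`.
#' @export
hypergeom_enrich <- function(query, gmt, universe) {
  stopifnot(inherits(gmt, "GeneSetCollection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0 || length(universe) == 0)
    stop("query and universe must be non-empty", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  big_n <- length(universe)
  k <- length(query)
  term_sizes <- vapply(gmt, function(g) length(intersect(g, universe)),
                       integer(1))
  overlaps <- vapply(gmt, function(g) length(intersect(g, query)),
                     integer(1))
  p <- stats::phyper(overlaps - 1, term_sizes, big_n - term_sizes, k,
                     lower.tail = FALSE)
  out <- data.frame(term_id = names(gmt), overlap = overlaps,
                    term_size = term_sizes, query_size = k,
                    p_value = p, bh_adjusted_p = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("EnrichmentProfile", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper around [stats::p.adjust()] (`method = "BH"`):
#' step-up adjusted values, capped at 1, monotone in raw-p order, returned
#' in the input order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Holm step-down adjustment
#'
#' As [bh_adjust()] but with `method = "holm"`.
#'
#' @inheritParams bh_adjust
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' Resampling null distribution of enrichment p-values
#'
#' Draws `n_draws` random gene sets of `set_size` from the universe
#' (without replacement within a draw), runs each through
#' [hypergeom_enrich()] with BH correction, and pools the per-term raw and
#' adjusted p-values. This is the null against which an observed
#' signature's enrichment profile is judged: if the signature's p-value
#' density is indistinguishable from the pooled null, its members are not
#' concentrated in particular terms beyond what any random platform draw
#' shows.
#'
#' @param universe Background gene population.
#' @param gmt A [gene_set_collection()].
#' @param set_size Size of each random set (default 150, the signature
#'   size).
#' @param n_draws Number of random draws (default 10000).
#' @param seed Integer seed; identical seeds give bitwise-identical
#'   profiles. The caller's RNG state is left untouched.
#' @return A list of class `NullProfile`: `n_draws`, `set_size`, `seed`,
#'   `pooled_p` (raw, length `n_draws * n_terms`), `pooled_bh`.
#' @export
resampling_null <- function(universe, gmt, set_size = 150, n_draws = 10000,
                            seed = NULL) {
  stopifnot(inherits(gmt, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (set_size > length(universe))
    stop("set_size exceeds the universe size", call. = FALSE)
  pools <- with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      q <- sample(universe, set_size)
      prof <- hypergeom_enrich(q, gmt, universe)
      list(p = prof$p_value, bh = prof$bh_adjusted_p)
    })
  })
  structure(list(n_draws = n_draws, set_size = set_size, seed = seed,
                 pooled_p = unlist(lapply(pools, `[[`, "p")),
                 pooled_bh = unlist(lapply(pools, `[[`, "bh"))),
            class = "NullProfile")
}

#' @export
print.NullProfile <- function(x, ...) {
  cat(sprintf("NullProfile: %d draws of size %d (%d pooled p-values)\n",
              x$n_draws, x$set_size, length(x$pooled_p)))
  invisible(x)
}

#' Compare an observed enrichment profile with the resampling null
#'
#' Two-sample Kolmogorov-Smirnov statistic between the observed p-value
#' vector and the pooled null p-values (asymptotic p; the p-values are
#' discrete, so the KS p is a summary, not an exact test). Kernel density
#' summaries of both vectors are returned for plotting the classic
#' observed-vs-null density overlay.
#'
#' @param observed An `EnrichmentProfile` (or a numeric p-value vector).
#' @param null A `NullProfile`.
#' @return A list with `statistic` (KS D), `p_value` and `densities`
#'   (`observed` and `null` [stats::density()] objects).
#' @export
compare_profiles <- function(observed, null) {
  stopifnot(inherits(null, "NullProfile"))
  obs_p <- if (inherits(observed, "EnrichmentProfile")) observed$p_value
           else as.numeric(observed)
  if (length(obs_p) == 0 || length(null$pooled_p) == 0)
    stop("degenerate input: empty p-value vector", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(obs_p, null$pooled_p,
                                        exact = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       densities = list(
         observed = stats::density(obs_p, from = 0, to = 1),
         null = stats::density(null$pooled_p, from = 0, to = 1)))
}
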