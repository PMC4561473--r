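# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain loops and textbook definitions only.

# All-pairs AUC: P(case score > control score) + 0.5 * P(tie).
oracle_auc <- function(scores, is_case) {
  pos <- scores[is_case]
  neg <- scores[!is_case]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive kNN majority vote, squared Euclidean, loops only.
# Ties in distance break towards the earlier training sample, vote ties
# towards the single nearest neighbour (mirrors the documented contract).
oracle_knn_predict <- function(train, train_case, x, k) {
  d <- numeric(ncol(train))
  for (s in seq_len(ncol(train))) d[s] <- sum((train[, s] - x)^2)
  nn <- order(d)[seq_len(k)]
  votes <- sum(train_case[nn])
  if (2 * votes == k) train_case[nn[1]] else votes > k / 2
}

# Holm step-down, from the definition.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Benjamini-Hochberg step-up, from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  rank_desc <- m:1
  for (i in seq_len(m)) {
    running <- min(running, m / rank_desc[i] * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Upper-tail hypergeometric P(X >= x) by full enumeration over all
# possible overlaps, using only choose().
oracle_hyper_upper <- function(x, universe_n, term_n, query_n) {
  tot <- 0
  for (j in max(0, query_n - (universe_n - term_n)):min(term_n, query_n))
    if (j >= x)
      tot <- tot + choose(term_n, j) * choose(universe_n - term_n,
                                              query_n - j)
  tot / choose(universe_n, query_n)
}

# Reference distribution for quantile normalization: sort each column,
# average across columns rank by rank.
oracle_qn_reference <- function(x) {
  s <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) s[, j] <- sort(x[, j])
  rowMeans(s)
}

# Small fixture builders -------------------------------------------------

make_em <- function(values, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- paste0("p", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  expression_matrix(values)
}

make_scores <- function(scaled, ids = paste0("s", seq_along(scaled))) {
  out <- data.frame(sample_id = ids,
                    raw_score = scaled * length(scaled),
                    scaled_score = scaled, stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <- 1L
  attr(out, "method") <- "median"
  class(out) <- c("GeneScoreResult", "data.frame")
  out
}

make_samples <- function(ids, groups, levels = unique(groups)) {
  sample_table(data.frame(sample_id = ids, group = groups,
                          stringsAsFactors = FALSE), levels = levels)
}

# Two trivially separated groups on every probe (offset in the case group).
make_separated_em <- function(n_probes, n_ref, n_case, offset = 5,
                              seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_probes * (n_ref + n_case)), n_probes)
  vals[, seq_len(n_case) + n_ref] <- vals[, seq_len(n_case) + n_ref] +
    offset
  make_em(vals)
}
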