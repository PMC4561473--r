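test_that("the rank score follows its definition on micro-examples", {
  # one down-regulated gene, expression (9, 5, 2):
  # highest expression -> rank 1, lowest -> rank n
  em <- make_em(matrix(c(9, 5, 2), 1, 3))
  sig <- signature_model("p1", "down", 0.95)
  sc <- compute_gene_score(em, sig)
  expect_equal(sc$raw_score, c(1, 2, 3))
  expect_equal(sc$scaled_score, c(1 / 3, 2 / 3, 1))

  # an up-regulated gene ranks the opposite way
  sig_up <- signature_model("p1", "up", 0.95)
  expect_equal(compute_gene_score(em, sig_up)$raw_score, c(3, 2, 1))

  # two genes, hand-enumerated: both assign ranks (1, 2, 3)
  em2 <- make_em(rbind(c(3, 2, 1), c(1, 2, 3)))
  sig2 <- signature_model(c("p1", "p2"), c("down", "up"), 0.9)
  sc2 <- compute_gene_score(em2, sig2)
  expect_equal(sc2$raw_score, c(1, 2, 3))
  expect_equal(attr(sc2, "n_genes_used"), 2)
})

test_that("in a 108-sample cohort the lowest expressor of a down gene scores 108", {
  set.seed(1)
  x <- sample(rnorm(108))
  em <- make_em(matrix(x, 1, 108))
  sc <- compute_gene_score(em, signature_model("p1", "down", 1))
  expect_equal(sc$raw_score[which.min(x)], 108)
  expect_equal(sc$scaled_score[which.min(x)], 1)
  expect_equal(sc$raw_score[which.max(x)], 1)
})

test_that("scores are invariant to monotone transforms and sample order", {
  set.seed(2)
  em <- make_em(matrix(rnorm(5 * 12), 5, 12))
  sig <- signature_model(paste0("p", 1:5),
                         c("down", "down", "up", "down", "up"), 0.9)
  sc <- compute_gene_score(em, sig)

  # strictly increasing per-gene transforms leave every score unchanged
  trans <- list(function(x) exp(x), function(x) 3 * x + 2,
                function(x) x^3, function(x) atan(x),
                function(x) x)
  vals2 <- em$exprs
  for (i in 1:5) vals2[i, ] <- trans[[i]](vals2[i, ])
  sc2 <- compute_gene_score(expression_matrix(vals2), sig)
  expect_equal(sc2$raw_score, sc$raw_score)

  # permuting samples permutes the scores with them
  perm <- sample(12)
  sc3 <- compute_gene_score(expression_matrix(em$exprs[, perm]), sig)
  expect_equal(sc3$raw_score[match(sc$sample_id, sc3$sample_id)],
               sc$raw_score)
})

test_that("per-gene assigned ranks sum to n(n+1)/2", {
  set.seed(3)
  n <- 17
  em <- make_em(matrix(rnorm(6 * n), 6, n))
  em$exprs[4, ] <- rep(em$exprs[4, 1:4], length.out = n)  # heavy ties
  for (g in 1:6) for (dir in c("down", "up")) {
    sc <- compute_gene_score(em, signature_model(paste0("p", g), dir, 1))
    expect_equal(sum(sc$raw_score), n * (n + 1) / 2)
  }
})

test_that("median and sum readings are both available", {
  set.seed(4)
  em <- make_em(matrix(rnorm(3 * 8), 3, 8))
  sig <- signature_model(paste0("p", 1:3), "down", 1)
  med <- compute_gene_score(em, sig)
  tot <- compute_gene_score(em, sig, method = "sum")
  expect_false(isTRUE(all.equal(med$raw_score, tot$raw_score)))
  expect_true(all(tot$scaled_score > 0 & tot$scaled_score <= 1))
  # with one gene the two readings coincide on raw ranks
  sig1 <- signature_model("p1", "down", 1)
  expect_equal(compute_gene_score(em, sig1)$raw_score,
               compute_gene_score(em, sig1, method = "sum")$raw_score)
})

test_that("absent signature genes are skipped, all-absent is an error", {
  em <- make_em(matrix(rnorm(8), 2, 4))
  sig <- signature_model(c("p1", "p2", "zz"), "down", 1)
  expect_message(sc <- compute_gene_score(em, sig), "1 signature gene")
  expect_equal(attr(sc, "n_genes_used"), 2)
  expect_error(compute_gene_score(em, signature_model("zz", "down", 1)),
               "no signature genes")
})

test_that("wilcoxon comparison reproduces the exact small-sample p", {
  sc <- make_scores(c(1, 2, 3, 4, 5, 6) / 6)
  st <- make_samples(sc$sample_id, rep(c("a", "b"), each = 3))
  cmp <- wilcoxon_compare(sc, st, "a", "b")
  expect_equal(cmp$statistic, 0)       # U of group a
  expect_equal(cmp$p_value, 0.1)       # 2 * 1/C(6,3)
  expect_lt(cmp$group_medians[["a"]], cmp$group_medians[["b"]])

  # symmetry under label swap
  cmp2 <- wilcoxon_compare(sc, st, "b", "a")
  expect_equal(cmp2$p_value, cmp$p_value)

  # identical groups: p = 1
  sc3 <- make_scores(rep(c(0.2, 0.5, 0.8), 2))
  st3 <- make_samples(sc3$sample_id, rep(c("a", "b"), 3))
  expect_equal(wilcoxon_compare(sc3, st3, "a", "b")$p_value, 1)

  expect_error(wilcoxon_compare(sc, st, "a", "zz"), "empty or unknown")
})

test_that("Kruskal-Wallis matches the textbook formula", {
  sc <- make_scores(c(1, 2, 3, 4, 5, 6) / 6)
  st <- make_samples(sc$sample_id, rep(c("a", "b", "c"), each = 2))
  kw <- kruskal_wallis(sc, st)
  # H = 12 / (N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2, no ties
  rbar <- c(1.5, 3.5, 5.5)
  h <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  expect_equal(kw$statistic, h)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(h, 2, lower.tail = FALSE))

  # identical groups: H = 0, p = 1
  sc2 <- make_scores(rep(c(0.1, 0.5, 0.9), 3))
  st2 <- make_samples(sc2$sample_id, rep(c("a", "b", "c"), each = 3))
  kw2 <- kruskal_wallis(sc2, st2)
  expect_equal(kw2$statistic, 0)
  expect_equal(kw2$p_value, 1)

  st_one <- make_samples(sc$sample_id, rep("a", 6))
  expect_error(kruskal_wallis(sc, st_one), "at least 2")
})

test_that("post hoc pairwise tests carry a correct Holm adjustment", {
  set.seed(5)
  sc <- make_scores(c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3)) / 10 + 0.5)
  st <- make_samples(sc$sample_id, rep(c("a", "b", "c"), each = 8))
  ph <- posthoc_mw_holm(sc, st)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$adjusted_p, oracle_holm(ph$p_value))
  expect_true(all(ph$adjusted_p >= ph$p_value))

  # single comparison: adjusted equals raw
  st2 <- make_samples(sc$sample_id, rep(c("a", "b"), 12))
  ph2 <- posthoc_mw_holm(sc, st2)
  expect_equal(ph2$adjusted_p, ph2$p_value)
})

test_that("score-covariate regression behaves like OLS", {
  sc <- make_scores(seq(0.1, 1, length.out = 10))
  fit <- suppressWarnings(
    regress_score(sc, 2 * seq(0.1, 1, length.out = 10) + 1))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.5)

  set.seed(6)
  cov <- rnorm(10)
  sc2 <- make_scores(runif(10))
  f1 <- regress_score(sc2, cov)
  f2 <- regress_score(sc2, -cov)
  expect_equal(f2$slope, -f1$slope)
  expect_equal(f2$r_squared, f1$r_squared)

  expect_error(regress_score(sc2, rep(1, 10)), "constant")

  # null covariate: r-squared small on average over replicates
  r2 <- vapply(1:40, function(s) {
    set.seed(100 + s)
    regress_score(make_scores(runif(30)), rnorm(30))$r_squared
  }, numeric(1))
  expect_lt(mean(r2), 0.12)   # E[r2] = 1/(n-1) under the null
})
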