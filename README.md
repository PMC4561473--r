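# agesig

Tools for discovering, validating and applying rank-based transcriptomic
signatures of **healthy ageing**.

Molecular markers of chronological age abound, but a marker of *healthy*
ageing — one that separates healthy old tissue from young tissue, keeps
working across muscle, brain and skin, and degrades in age-related
disease — needs a different construction: a classifier-derived gene
panel with a fixed direction of regulation per gene, selected once on a
single training cohort and then only ever evaluated on independent data.
`agesig` implements that pipeline for bioinformaticians who want to
build such signatures from their own two-group cohorts, or stress-test
the methodology on simulated ones:

* **Signature selection** — a nested hold-out LOOCV loop: for every
  ordered pair of samples both are held out, probes are ranked by an
  empirical-Bayes moderated t-statistic
  (s̃²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀ + dᵍ), hyperparameters by digamma/trigamma
  moment-matching), the top 200 probes form the feature space, and the
  held-out sample is classified by a k-nearest-neighbour vote. Each
  probe is tallied by the share of all n(n−1) decisions it was correctly
  involved in; the top probes above the 90 % threshold (150 at most, by
  default) become the directional signature, with an extended ≥70 % list
  attached.
* **Classification** — strict external validation against a reference
  cohort of known samples (`knn_classify_external`), within-cohort LOOCV
  (`knn_classify_loocv`), and ROC/AUC evaluation via the rank formula
  AUC = U/(n₊n₋).
* **Gene score** — the per-subject healthy-ageing score: per signature
  gene, samples are ranked (down-regulated gene: highest expression →
  rank 1, lowest → rank n; up-regulated: the reverse), and a subject's
  score is the median of its per-gene ranks, scaled by cohort size.
  Non-parametric group statistics (Wilcoxon, Kruskal–Wallis, post hoc
  Mann–Whitney with Holm) and covariate regression included.
* **Enrichment** — hypergeometric over-representation per gene-set term,
  judged against a resampling null built from thousands of random
  signature-sized draws from the platform, with Benjamini–Hochberg
  correction and Kolmogorov–Smirnov profile comparison.
* **Synthetic cohorts** — generators for training, validation and
  case–control cohorts with planted ground truth (directional effects,
  multi-locus probes, cross-platform probe attrition), so the entire
  pipeline is testable without any array downloads.

See the methods vignette (`vignettes/healthy-ageing-signature.Rmd`) for
the model details and design rationale.

## Worked example

Discover a signature on a simulated training cohort, validate it
externally, and score an independent case–control cohort:

```r
library(agesig)

coh  <- simulate_training_cohort(cohort_spec(seed = 42))
perf <- nested_loocv_select(coh$matrix, coh$samples)   # 870 decisions
sig  <- build_signature(perf, coh$matrix, coh$samples, coh$annotation)
sig
#> SignatureModel: 112 probes (82 down, 30 up)
#> note: nested LOOCV: 870 decisions, perf >= 0.9, top 112

# external validation on an independent 20 v 20 cohort
val <- simulate_validation_cohort(coh$truth,
                                  cohort_spec(n_young = 20, n_old = 20,
                                              seed = 43))
res <- knn_classify_external(coh$matrix, coh$samples, val$matrix, sig,
                             k = 5, test_labels = val$samples)
roc_auc(res)
#> RocCurve: AUC = 0.9988 (20 cases vs 20 controls)

# score a case-control cohort on a different platform (22/150 genes lost
# in mapping) and compare groups
cc     <- simulate_case_control(coh$truth, case_control_spec(seed = 44))
truth  <- signature_model(coh$truth$probe_id, coh$truth$direction, 1)
mapped <- map_signature(truth, coh$annotation, cc$annotation)
scores <- compute_gene_score(cc$matrix, mapped)
wilcoxon_compare(scores, cc$samples, "control", "case")
#> GroupComparison: statistic = 3144, p = 2.455e-19
#> group medians: control = 0.5783, case = 0.3913
```

The 112-probe signature recovers the planted direction structure (82
down-regulated), classifies the fresh cohort essentially perfectly
(AUC 0.999), and the mapped signature's gene score separates controls
from attenuated cases decisively — controls scoring higher, as a
healthy-ageing score should.

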