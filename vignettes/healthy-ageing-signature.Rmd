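---
title: "Discovering and scoring a healthy-ageing expression signature"
author: "agesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and scoring a healthy-ageing expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agesig)
```

# Overview

`agesig` implements a classifier-based pipeline for extracting a
multi-tissue transcriptomic signature of healthy ageing from a two-group
(young vs old) expression cohort, and for applying that signature to new
cohorts — as a kNN classifier of age group, and as a per-subject
rank-based *gene score* whose distribution can be compared between
clinical groups (for instance age-matched controls versus people with
mild cognitive impairment or Alzheimer's disease). The guiding design
principle is strict separation of training and validation: the training
cohort is used exactly once, to fix the probe list and each probe's
direction of regulation, and every later evaluation runs on independent
data.

This vignette documents the methods as implemented, the tunable
parameters and their defaults, the synthetic-cohort generator used by the
test-suite, and the numerical and design choices that were genuinely
open.

# Signature selection

## Moderated t-ranking

Probes are ranked within each training fold by an empirical-Bayes
moderated t-statistic. For probe $g$ with pooled two-sample variance
$s_g^2$ on $d_g = n_1 + n_2 - 2$ residual degrees of freedom, the
posterior variance shrinks towards a prior $s_0^2$ with prior degrees of
freedom $d_0$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
\tilde t_g = \frac{\bar x_{g,2} - \bar x_{g,1}}
                  {\tilde s_g \sqrt{1/n_1 + 1/n_2}}.$$

The hyperparameters $(d_0, s_0^2)$ are estimated by moment-matching the
between-probe distribution of $\log s_g^2$ under the scaled-F variance
model: with $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the mean of
$e_g$ identifies $s_0^2$ and the excess variance of $e_g$ over
$\psi'(d_g/2)$ identifies $d_0$ through the trigamma function (solved by
Newton iteration). When the between-probe spread of $\log s_g^2$ is no
larger than its sampling spread, $d_0 = \infty$ and every probe is
assigned the common prior variance; if the moment equations cannot be
solved at all the prior degrees of freedom fall back to 0, which
reproduces the ordinary pooled t-statistic (`moderated_t(..., prior_df =
0)` forces this limit). The test-suite cross-checks the implementation
against `limma::eBayes` on shared fixtures.

## The nested hold-out loop

`nested_loocv_select()` reconstructs the double hold-out as all ordered
pairs $(i, j)$ of distinct samples: both are removed, the moderated t on
the remaining $n - 2$ samples ranks the probes, the top `n_inner`
(default 200) define the feature space, and sample $i$ is classified by
a $k$-nearest-neighbour majority vote (default $k = 5$, Euclidean
distance on per-probe z-scores estimated from the retained samples only).
With $n$ samples this yields exactly $n(n-1)$ decisions and
$n(n-1) \cdot n_\text{inner}$ probe-evaluation events — 174,000 for the
default 30-sample training design. Each decision's correctness is
credited to every probe in its feature space.

Two per-probe summaries come out of the tally:

* `performance` = correct / appearances, the accuracy of the decisions
  the probe contributed to;
* `decision_share` = correct / $n(n-1)$, the share of *all* hold-out
  decisions the probe was correctly involved in.

`build_signature()` thresholds and ranks on the **decision share**. This
was a genuinely open design point and deserves its rationale: when the
held-out accuracy is high (which it is whenever a real signature is
present), per-probe accuracy saturates near 1 and its ranking is
dominated by rarely-selected probes that happened to be lucky on a
handful of decisions, while probes stable enough to be selected in every
single fold are penalised for sharing in the few wrong decisions. The
decision share rewards exactly the property the signature needs —
stable selection across folds carried by correct classifications — and
it is the reading under which thresholds such as "involved in more than
90 % of correct decisions" produce a short, stable top list together
with a several-fold larger relaxed list (the `relaxed` attribute, default
threshold 0.70).

Before thresholding, probes flagged as targeting multiple genomic loci
are removed, as are probes appearing in fewer than
`min_appearance_frac` (default 10 %) of decisions. Each retained probe's
direction is fixed once, on the full training matrix: `down` if the old
group's mean is below the young group's. The cap `top_n` (default 150)
is applied after ranking; if fewer probes survive the thresholds the
signature is simply shorter, with a warning — it is never padded.

## What recovery can and cannot reach

Under the default synthetic design (15 vs 15 samples, 2,000 probes, 100
planted at one within-group standard deviation) the selection is close to
the information-theoretic ceiling rather than to perfection: a planted
probe's expected absolute t is about 2.7 with unit spread, so its
distribution overlaps the upper tail of the 1,900 null probes
substantially. Empirically the survivor list is roughly 100–115 probes of
which ~60–65 % are planted — essentially the same purity as an
*omniscient* ranking by the full-data moderated t (whose top 100 is
~65 % planted on the same data). Recovered directions for truly planted
probes are essentially always correct. Consequently the selected list's
down-regulated fraction sits around 0.70 rather than the planted 0.85,
because the false-positive half carries no directional preference. At
larger effect sizes or probe counts closer to a real array the purity
rises quickly; the defaults were chosen to mirror the scale of the
original training design, not to flatter the selector.

# Classification and evaluation

`knn_classify_external()` implements external validation in the strict
sense: a reference cohort of known samples defines the signature feature
space and its per-probe scaling (z-scores from reference mean and
standard deviation), and each unknown sample is classified independently
by majority vote of its $k$ nearest reference samples. The reference is
never re-fit. This per-probe reference z-scoring is a deliberate,
documented simplification of frozen cross-study normalization; it
absorbs cohort-level baseline shifts only through the vote's robustness,
which is why validation cohorts simulated with fresh per-probe baselines
still classify well at realistic effect sizes. `knn_classify_loocv()`
covers the within-cohort variant (used when platforms differ too much
for a shared reference), re-estimating the scaling from the $n-1$
retained samples at every fold.

`vote_score` — the fraction of case-labelled neighbours — is the ROC
ranking variable. `roc_auc()` computes the AUC by the rank formula
$AUC = U / (n_\text{pos} n_\text{neg})$ with ties counting one half,
which is exactly the all-pairs probability of correct ordering; the
test-suite verifies this against a brute-force enumeration and against
`pROC`. Vote ties (possible for even $k$, which draws a warning) resolve
to the single nearest neighbour's label; distance ties break towards the
lower sample index, making the whole pipeline deterministic.

# The healthy-ageing gene score

For each signature gene, cohort samples are ranked so that the sample
whose expression looks most like healthy old tissue gets the highest
rank: for a down-regulated gene the highest-expressing sample receives
rank 1 and the lowest rank $n$; for an up-regulated gene the reverse.
Ties receive average ranks, so each gene's assigned ranks always sum to
$n(n+1)/2$. A sample's raw score is the **median** of its per-gene ranks
— the median gives every gene equal weight and is insensitive to any
strictly monotone per-gene transform — and the scaled score divides by
$n$ so cohorts of different sizes share a $(0, 1]$ axis. A summed
variant (`method = "sum"`) is exposed for sensitivity analysis because
the two readings ("median rank" vs "summed rank") are both defensible;
the median is the default. Scores are cohort-relative by construction:
adding or removing samples changes every score, and the documentation
says so rather than pretending otherwise.

Group statistics are deliberately non-parametric, matching the score's
rank nature: `wilcoxon_compare()` (exact for small tie-free samples),
`kruskal_wallis()` with tie correction for 3 or more unequal groups,
`posthoc_mw_holm()` for pairwise contrasts under the Holm step-down, and
`regress_score()` for ordinary least squares against a clinical
covariate. All of these delegate to the battle-tested `stats` routines;
the package's tests pin them against hand-computed textbook values.

# Enrichment against a resampling null

`hypergeom_enrich()` computes upper-tail hypergeometric
over-representation p-values for each term of a gene-set collection,
with the whole platform annotation as the background universe.
`resampling_null()` draws `n_draws` (default 10,000; the test-suite uses
500) random signature-sized gene sets from the universe, runs each
through the same enrichment (including Benjamini–Hochberg correction),
and pools the p-values. `compare_profiles()` summarises the observed
profile against the pooled null with a two-sample Kolmogorov–Smirnov
statistic and returns kernel-density summaries for the classic
observed-vs-null density overlay. The KS statistic is an artifact
choice: the original analysis only plotted the densities, and no claim
beyond the KS summary is made here. Note that with a realistic number of
terms the profile has only dozens of p-values, so the KS comparison has
real power only against profile-wide distortions, not against a single
enriched term.

# Synthetic cohorts

The generator exists so that every stage is testable end to end without
any external download, and its defaults *are* the study conditions the
tests run under:

| parameter | default | meaning |
|---|---|---|
| `n_young`, `n_old` | 15, 15 | training group sizes |
| `n_probes` | 2,000 | platform size (scaled down from ~54,000) |
| `n_signal` | 100 | planted signature size |
| `frac_down` | 0.85 | planted down-regulated fraction (deterministic allocation) |
| `effect_size` | 1.0 | old-group shift in units of `noise_sd` |
| `noise_sd` | 1.0 | within-group Gaussian noise, log2 scale |
| `baseline_mean` | 7 | per-probe baselines ~ Normal(7, 1), typical log2 intensities |
| `multi_locus_frac` | 0.05 | probes flagged multi-locus, signal included |

Expression is `baseline + group shift + Gaussian noise`, independent
across probes. Validation cohorts redraw baselines and noise (a new
laboratory), scale the planted effects by `1 - tissue_attenuation`, and
may change the group sizes. Case-control cohorts place everyone in the
old age range, give controls the full old-direction signature and cases
an attenuated one (`attenuation`, default 0.5), and emit a destination
platform (`ILMN_`-style probe ids) from which a configurable fraction of
signature genes is absent — so applying a training signature exercises
the symbol-level `map_signature()` attrition exactly as a real
cross-platform transfer would (dropping 22 of 150 genes reproduces the
128-gene mapped list).

What the generator does **not** emulate: probe-probe correlation
(available behind no flag — effects are independent by design and the
rank score's behaviour under correlated blocks is therefore untested
here), batch structure, spatial artifacts, intensity-dependent variance
and count-based RNA-seq noise. Passing tests demonstrate the pipeline's
internal correctness and its behaviour under the stated Gaussian model;
they do not certify performance on real arrays.

All randomness flows from one integer seed per generator call through a
local RNG scope, so calls are reproducible and never disturb the
caller's random stream.

# Numerical choices and degenerate inputs

* Quantile normalization forces each column onto the per-rank mean
  across columns; tied values receive the mean of the reference values
  at their occupied ranks. This tie dialect is implemented directly (it
  differs from interpolation-based variants for ties of size > 2) and
  agrees with `limma::normalizeQuantiles` exactly on tie-free data.
* `scale_center()` uses the $n-1$ denominator and drops zero-variance
  rows with a warning rather than producing NaN.
* Expression files are parsed with an explicit orientation flag (probes
  in rows or samples in rows), never guessed; missing values are
  rejected by default, with per-probe median imputation behind a flag.
  Values are written with 17 significant digits so read/write round-trips
  are bit-exact.
* Whether scaling is per-probe or per-sample was left open by the
  original description; per-probe is the default and per-sample sits
  behind `axis = "sample"`.
* `merge_signatures()` keeps the first signature's direction on a
  collision (with a warning) and the larger performance value.
* Zero-variance features inside a kNN fold contribute zero distance
  rather than dividing by zero.

# Known limitations

* The exact topology of the original nested loop is under-determined by
  its description; the all-ordered-pairs reconstruction matches the
  published decision and event counts (870 and ~180,000 at the original
  cohort size) but is not asserted to be the authors' code.
* Held-out accuracy across the $n(n-1)$ decisions recycles each sample
  ~$2(n-1)$ times, so its sampling spread is far wider than a binomial
  on $n(n-1)$ trials would suggest — about $\sqrt{2(n-1)}$ wider. Checks
  that treat the decision count as independent trials are miscalibrated
  and will reject a correct null in a large fraction of seeds; the
  honest effective unit is the sample, and the package's own null tests
  average over replicate cohorts for that reason. Relatedly, removing a
  same-group partner array biases the held-out vote slightly *against*
  the true label (the held-out sample's group is under-represented among
  the neighbours), so null accuracy sits a few points below 0.5 rather
  than at it.
* Reference z-scoring is not a substitute for proper cross-study
  normalization when array generations differ strongly; the
  within-cohort LOOCV classifier is the fallback, as in the original
  skin analysis.
* The gene score is cohort-relative; scores from different cohorts are
  comparable only after the within-cohort scaling, and only as ranks.

# Problem sizes used by the test-suite

The test-suite and the acceptance script run the full pipeline at the
generator defaults (30 samples, 2,000 probes; 870 hold-out decisions and
174,000 probe-evaluation events per selection run), 50 case-control
replicates at 70 vs 45, 200 null score replicates at 20 vs 20, and a
500-draw enrichment null over 50 terms. These sizes were chosen so the
whole suite exercises every stage end to end in a few minutes on a
single core while keeping each check's statistical resolution adequate
for the property it tests.
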