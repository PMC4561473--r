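#' Specification of a synthetic two-group cohort
#'
#' Defaults mirror the scaled-down study conditions used throughout the
#' package's tests: a 15 vs 15 young/old training design with 2,000 probes
#' of which 100 carry a planted age signature, 85 percent of it
#' down-regulated with age, at an effect of one within-group standard
#' deviation on the log2 scale.
#'
#' @param n_young,n_old Group sizes (each at least 2).
#' @param n_probes Total probes on the simulated platform.
#' @param n_signal Planted signature size (`<= n_probes`).
#' @param frac_down Fraction of signal probes down-regulated with age; the
#'   number of down probes is `round(frac_down * n_signal)`, a
#'   deterministic allocation.
#' @param effect_size Mean shift in the old group, in units of
#'   `noise_sd`.
#' @param noise_sd Within-group standard deviation of the Gaussian
#'   log-intensity noise.
#' @param baseline_mean Mean of the per-probe baseline distribution
#'   (baselines are drawn `Normal(baseline_mean, 1)`, typical of log2
#'   microarray intensities around 7).
#' @param multi_locus_frac Fraction of probes flagged as targeting
#'   multiple genomic loci (flags are assigned at random, so some may land
#'   on signal probes — deliberately, to exercise their removal).
#' @param seed Integer seed; all randomness in the simulators flows from
#'   it, with no global RNG state disturbed.
#' @return A list of class `CohortSpec`.
#' @export
cohort_spec <- function(n_young = 15, n_old = 15, n_probes = 2000,
                        n_signal = 100, frac_down = 0.85, effect_size = 1.0,
                        noise_sd = 1.0, baseline_mean = 7,
                        multi_locus_frac = 0.05, seed = 1) {
  stopifnot(n_young >= 2, n_old >= 2, n_signal <= n_probes,
            frac_down >= 0, frac_down <= 1, effect_size >= 0, noise_sd > 0,
            multi_locus_frac >= 0, multi_locus_frac < 1)
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 n_probes = as.integer(n_probes),
                 n_signal = as.integer(n_signal), frac_down = frac_down,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 multi_locus_frac = multi_locus_frac,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Specification of a synthetic case-control cohort
#'
#' Emulates blood case-control designs in which the healthy-ageing
#' signature is attenuated in cases: controls carry the full old-direction
#' shift, cases carry `(1 - attenuation)` of it. Optionally a fraction of
#' signature probes is absent from the simulated destination platform,
#' exercising cross-platform signature attrition.
#'
#' @param n_control,n_case Group sizes.
#' @param attenuation In `[0, 1]`: fraction of the old-direction shift
#'   removed in cases (0 = cases identical to controls in expectation over
#'   the signature, 1 = signature fully absent in cases).
#' @param platform_dropout In `[0, 1)`: fraction of signature probes
#'   absent from the destination platform; the number dropped is
#'   `round(platform_dropout * n_signal)`.
#' @param seed Integer seed.
#' @return A list of class `CaseControlSpec`.
#' @export
case_control_spec <- function(n_control = 70, n_case = 45,
                              attenuation = 0.5, platform_dropout = 0,
                              seed = 1) {
  stopifnot(n_control >= 2, n_case >= 2, attenuation >= 0, attenuation <= 1,
            platform_dropout >= 0, platform_dropout < 1)
  structure(list(n_control = as.integer(n_control),
                 n_case = as.integer(n_case), attenuation = attenuation,
                 platform_dropout = platform_dropout,
                 seed = as.integer(seed)),
            class = "CaseControlSpec")
}

sim_probe_ids <- function(n) sprintf("P%05d", seq_len(n))
sim_gene_symbols <- function(n) sprintf("GENE%05d", seq_len(n))

# Planted truth shared by all simulators derived from one training spec.
make_truth <- function(spec) {
  n_down <- round(spec$frac_down * spec$n_signal)
  signal_idx <- seq_len(spec$n_signal)      # planted probes lead the panel
  direction <- rep("up", spec$n_signal)
  direction[seq_len(n_down)] <- "down"
  effect <- ifelse(direction == "down", -1, 1) *
    spec$effect_size * spec$noise_sd
  truth <- data.frame(probe_id = sim_probe_ids(spec$n_probes)[signal_idx],
                      gene_symbol = sim_gene_symbols(spec$n_probes)[signal_idx],
                      direction = direction, effect = effect,
                      stringsAsFactors = FALSE)
  attr(truth, "n_probes") <- spec$n_probes
  attr(truth, "noise_sd") <- spec$noise_sd
  attr(truth, "baseline_mean") <- spec$baseline_mean
  class(truth) <- c("TruthRecord", "data.frame")
  truth
}

sim_matrix <- function(n_probes, effects_by_col, noise_sd, baseline) {
  n <- ncol(effects_by_col)
  vals <- baseline + effects_by_col +
    matrix(stats::rnorm(n_probes * n, sd = noise_sd), n_probes, n)
  vals
}

#' Simulate a two-group training cohort
#'
#' Generates `value[g, s] = baseline_g + I(s is old) * effect_g + noise`,
#' with per-probe baselines `Normal(baseline_mean, 1)`, independent
#' Gaussian noise, and planted effects of
#' `+/- effect_size * noise_sd` for the signal probes (sign per the
#' planted direction; `down` means lower expression in the old group).
#' Young ages are drawn from 19-28 years and old ages from 59-77 years. A
#' `multi_locus_frac` fraction of probes (chosen at random, signal probes
#' included) is flagged multi-locus in the annotation. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `matrix` ([expression_matrix()]),
#'   `samples` ([sample_table()]), `annotation` ([probe_annotation()]) and
#'   `truth` (a `TruthRecord` data frame of planted probe ids, directions
#'   and effects).
#' @export
simulate_training_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  truth <- make_truth(spec)
  n <- spec$n_young + spec$n_old
  is_old <- c(rep(FALSE, spec$n_young), rep(TRUE, spec$n_old))
  with_seed(spec$seed, {
    baseline <- stats::rnorm(spec$n_probes, spec$baseline_mean, 1)
    effects <- numeric(spec$n_probes)
    effects[seq_len(spec$n_signal)] <- truth$effect
    eff_cols <- outer(effects, as.numeric(is_old))
    vals <- sim_matrix(spec$n_probes, eff_cols, spec$noise_sd, baseline)
    dimnames(vals) <- list(sim_probe_ids(spec$n_probes),
                           c(sprintf("Y%03d", seq_len(spec$n_young)),
                             sprintf("O%03d", seq_len(spec$n_old))))
    ml <- rep(FALSE, spec$n_probes)
    n_ml <- round(spec$multi_locus_frac * spec$n_probes)
    if (n_ml > 0) ml[sample(spec$n_probes, n_ml)] <- TRUE
    ages <- ifelse(is_old, sample(59:77, n, replace = TRUE),
                   sample(19:28, n, replace = TRUE))
    list(
      matrix = expression_matrix(vals, transform_log = "simulated_log2"),
      samples = sample_table(data.frame(
        sample_id = colnames(vals),
        group = ifelse(is_old, "old", "young"),
        age = ages, stringsAsFactors = FALSE),
        levels = c("young", "old")),
      annotation = probe_annotation(data.frame(
        probe_id = sim_probe_ids(spec$n_probes),
        gene_symbol = sim_gene_symbols(spec$n_probes),
        multi_locus = ml, platform = "SIMU133",
        stringsAsFactors = FALSE)),
      truth = truth)
  })
}

#' Simulate an independent validation cohort
#'
#' Fresh per-probe baselines and fresh noise (emulating a new laboratory
#' and cohort), with the planted effects scaled by
#' `(1 - tissue_attenuation)`; sizes come from `spec` (`n_young`,
#' `n_old`). At `tissue_attenuation = 1` the cohort carries no age signal
#' at all.
#'
#' @param truth The `TruthRecord` from [simulate_training_cohort()].
#' @param spec A [cohort_spec()] giving sizes, noise and seed for the new
#'   cohort (signal fields are ignored; the truth defines them).
#' @param tissue_attenuation In `[0, 1]`.
#' @return A list with `matrix` and `samples`.
#' @export
simulate_validation_cohort <- function(truth, spec, tissue_attenuation = 0) {
  stopifnot(inherits(truth, "TruthRecord"), inherits(spec, "CohortSpec"),
            tissue_attenuation >= 0, tissue_attenuation <= 1)
  n_probes <- attr(truth, "n_probes")
  n <- spec$n_young + spec$n_old
  is_old <- c(rep(FALSE, spec$n_young), rep(TRUE, spec$n_old))
  with_seed(spec$seed, {
    baseline <- stats::rnorm(n_probes, attr(truth, "baseline_mean"), 1)
    effects <- numeric(n_probes)
    effects[match(truth$probe_id, sim_probe_ids(n_probes))] <-
      truth$effect * (1 - tissue_attenuation)
    eff_cols <- outer(effects, as.numeric(is_old))
    vals <- sim_matrix(n_probes, eff_cols, spec$noise_sd, baseline)
    dimnames(vals) <- list(sim_probe_ids(n_probes),
                           c(sprintf("VY%03d", seq_len(spec$n_young)),
                             sprintf("VO%03d", seq_len(spec$n_old))))
    list(
      matrix = expression_matrix(vals, transform_log = "simulated_log2"),
      samples = sample_table(data.frame(
        sample_id = colnames(vals),
        group = ifelse(is_old, "old", "young"), stringsAsFactors = FALSE),
        levels = c("young", "old")))
  })
}

#' Simulate a case-control cohort on a destination platform
#'
#' All subjects are "old"; controls carry the full planted old-direction
#' signature, cases carry it attenuated by `spec$attenuation`. The emitted
#' matrix and annotation live on a destination platform (`ILMN_`-style
#' probe ids sharing the training gene symbols), from which
#' `round(platform_dropout * n_signal)` signature genes are absent — so
#' carrying a training signature over requires [map_signature()] and
#' incurs realistic attrition.
#'
#' @param truth The `TruthRecord` from [simulate_training_cohort()].
#' @param spec A [case_control_spec()].
#' @return A list with `matrix`, `samples` (groups `control`/`case`) and
#'   `annotation` (destination platform).
#' @export
simulate_case_control <- function(truth, spec) {
  stopifnot(inherits(truth, "TruthRecord"),
            inherits(spec, "CaseControlSpec"))
  n_probes <- attr(truth, "n_probes")
  n <- spec$n_control + spec$n_case
  is_control <- c(rep(TRUE, spec$n_control), rep(FALSE, spec$n_case))
  with_seed(spec$seed, {
    n_drop <- round(spec$platform_dropout * nrow(truth))
    dropped <- if (n_drop > 0) sample(nrow(truth), n_drop) else integer(0)
    drop_genes <- truth$gene_symbol[dropped]
    keep <- !(sim_gene_symbols(n_probes) %in% drop_genes)

    baseline <- stats::rnorm(n_probes, attr(truth, "baseline_mean"), 1)
    effects <- numeric(n_probes)
    sig_idx <- match(truth$probe_id, sim_probe_ids(n_probes))
    effects[sig_idx] <- truth$effect
    # controls: full old-direction shift; cases: attenuated
    carrier <- ifelse(is_control, 1, 1 - spec$attenuation)
    eff_cols <- outer(effects, carrier)
    vals <- sim_matrix(n_probes, eff_cols, attr(truth, "noise_sd"),
                       baseline)
    dst_ids <- sprintf("ILMN_%05d", seq_len(n_probes))
    dimnames(vals) <- list(dst_ids,
                           c(sprintf("CTL%03d", seq_len(spec$n_control)),
                             sprintf("CASE%03d", seq_len(spec$n_case))))
    vals <- vals[keep, , drop = FALSE]
    list(
      matrix = expression_matrix(vals, transform_log = "simulated_log2"),
      samples = sample_table(data.frame(
        sample_id = colnames(vals),
        group = ifelse(is_control, "control", "case"),
        stringsAsFactors = FALSE), levels = c("control", "case")),
      annotation = probe_annotation(data.frame(
        probe_id = dst_ids[keep],
        gene_symbol = sim_gene_symbols(n_probes)[keep],
        multi_locus = FALSE, platform = "SIMILMN",
        stringsAsFactors = FALSE)))
  })
}

#' Simulate a gene-set collection
#'
#' Terms are sampled uniformly (without replacement within a term) from
#' the universe, with sizes uniform over `size_range`. Optionally one
#' extra term is seeded from a supplied gene set, creating genuine
#' enrichment for queries overlapping it.
#'
#' @param universe Character vector of gene symbols.
#' @param n_terms Number of random terms.
#' @param size_range Length-2 integer vector of admissible term sizes.
#' @param planted_term_from Optional character vector; when given, a term
#'   `"PLANTED"` with exactly these genes is appended.
#' @param seed Integer seed.
#' @return A [gene_set_collection()].
#' @export
simulate_gmt <- function(universe, n_terms = 50, size_range = c(10, 100),
                         planted_term_from = NULL, seed = 1) {
  universe <- unique(as.character(universe))
  stopifnot(max(size_range) <= length(universe), min(size_range) >= 1)
  with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_terms,
                    replace = TRUE)
    sets <- lapply(sizes, function(sz) sample(universe, sz))
    names(sets) <- sprintf("T%04d", seq_len(n_terms))
    desc <- stats::setNames(sprintf("random term %d", seq_len(n_terms)),
                            names(sets))
    if (!is.null(planted_term_from)) {
      sets$PLANTED <- unique(as.character(planted_term_from))
      desc <- c(desc, PLANTED = "planted term")
    }
    gene_set_collection(sets, descriptions = desc)
  })
}
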