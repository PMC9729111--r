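#' Simulation configuration for the synthetic post-GWAS world
#'
#' A single validated configuration object drives every generator in the
#' synthetic-data module. The same seed and configuration always produce
#' byte-identical outputs; each generator derives its own RNG sub-stream
#' from the seed, so calling the generators in a different order does not
#' change any of them.
#'
#' Defaults describe a desk-scale analogue of a large coronary-artery-
#' disease case-control meta-analysis: polygenic liability architecture
#' with weak per-allele log-odds effects, block-structured LD, a baseline
#' population risk of 0.0719, ten candidate tissues of which one carries a
#' five-fold functional-annotation enrichment around causal variants, a
#' cross-ancestry effect correlation of 0.6, and eight binary locus-to-gene
#' predictors with per-predictor sensitivity/specificity.
#'
#' @param seed integer master seed; fully determines all outputs.
#' @param n_variants number of variants in the panel.
#' @param n_blocks number of independent LD blocks.
#' @param block_rho AR(1) correlation parameter within a block, in `[0, 1)`.
#' @param n_causal number of causal variants (`<= n_variants`; default 50,
#'   capped at `n_variants`).
#' @param causal_beta_sd standard deviation of true per-allele log-odds
#'   effects at causal variants.
#' @param n_studies number of contributing case-control studies.
#' @param per_study_cases,per_study_controls per-study case/control counts
#'   (scalar or length `n_studies`).
#' @param baseline_risk baseline population risk K, in (0, 1).
#' @param annotation_enrichment fold enrichment (>= 1) of annotation odds at
#'   causal versus non-causal variants, recycled to `n_tissues`; the
#'   default enriches the first tissue five-fold and leaves the rest null.
#' @param annotation_coverage background annotation coverage per tissue,
#'   in `[0, 1]`.
#' @param n_tissues number of annotation tracks (tissues).
#' @param cross_ancestry_r true correlation of per-variant causal effects
#'   between the two simulated ancestries, in `[-1, 1]`.
#' @param predictor_sensitivity,predictor_specificity length-8 vectors of
#'   per-predictor probabilities for the locus-to-gene evidence generator.
#' @param cohort_n number of individuals in the prospective cohort.
#' @param followup_years length of cohort follow-up (event times for cases
#'   are uniform over this window).
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_variants = 100, n_blocks = 10)
#' cfg$block_rho
sim_config <- function(seed = 1L,
                       n_variants = 5000L,
                       n_blocks = 50L,
                       block_rho = 0.9,
                       n_causal = min(50L, n_variants),
                       causal_beta_sd = 0.05,
                       n_studies = 4L,
                       per_study_cases = 20000L,
                       per_study_controls = 80000L,
                       baseline_risk = 0.0719,
                       annotation_enrichment = c(5, rep(1, 9)),
                       annotation_coverage = 0.1,
                       n_tissues = 10L,
                       cross_ancestry_r = 0.6,
                       predictor_sensitivity = rep(0.8, 8),
                       predictor_specificity = rep(0.95, 8),
                       cohort_n = 20000L,
                       followup_years = 5) {
  cfg <- list(
    seed = as.integer(seed),
    n_variants = as.integer(n_variants),
    n_blocks = as.integer(n_blocks),
    block_rho = block_rho,
    n_causal = as.integer(n_causal),
    causal_beta_sd = causal_beta_sd,
    n_studies = as.integer(n_studies),
    per_study_cases = rep_len(as.integer(per_study_cases), n_studies),
    per_study_controls = rep_len(as.integer(per_study_controls), n_studies),
    baseline_risk = baseline_risk,
    annotation_enrichment = rep_len(annotation_enrichment, n_tissues),
    annotation_coverage = rep_len(annotation_coverage, n_tissues),
    n_tissues = as.integer(n_tissues),
    cross_ancestry_r = cross_ancestry_r,
    predictor_sensitivity = predictor_sensitivity,
    predictor_specificity = predictor_specificity,
    cohort_n = as.integer(cohort_n),
    followup_years = followup_years
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_variants < 1) stop_input("n_variants must be positive")
  if (cfg$n_blocks < 1) stop_input("n_blocks must be >= 1")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) {
    stop_input("block_rho must lie in [0, 1)")
  }
  if (cfg$n_causal > cfg$n_variants) {
    stop_input("n_causal (%d) exceeds n_variants (%d)",
               cfg$n_causal, cfg$n_variants)
  }
  if (cfg$n_causal < 0) stop_input("n_causal must be non-negative")
  if (cfg$baseline_risk <= 0 || cfg$baseline_risk >= 1) {
    stop_input("baseline_risk must lie in (0, 1)")
  }
  if (any(cfg$annotation_enrichment < 1)) {
    stop_input("annotation_enrichment folds must be >= 1")
  }
  if (any(cfg$annotation_coverage < 0 | cfg$annotation_coverage > 1)) {
    stop_input("annotation_coverage must lie in [0, 1]")
  }
  if (abs(cfg$cross_ancestry_r) > 1) {
    stop_input("cross_ancestry_r must lie in [-1, 1]")
  }
  probs <- c(cfg$predictor_sensitivity, cfg$predictor_specificity)
  if (length(cfg$predictor_sensitivity) != 8 ||
      length(cfg$predictor_specificity) != 8) {
    stop_input("predictor sensitivity/specificity must be length-8 vectors")
  }
  if (any(probs < 0 | probs > 1)) {
    stop_input("predictor probabilities must lie in [0, 1]")
  }
  if (any(cfg$per_study_cases < 1) || any(cfg$per_study_controls < 1)) {
    stop_input("per-study case/control counts must be positive")
  }
  invisible(cfg)
}
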