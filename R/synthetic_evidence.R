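# Fixed predictor order used throughout the consensus framework.
PREDICTORS <- c("clinvar_monogenic", "drug_or_MR", "pops_top2",
                "eqtl_highLD", "mouse_ko", "protein_altering_highLD",
                "rare_variant_assoc", "nearest_gene")

#' Simulate a locus-by-gene-by-predictor evidence matrix
#'
#' Each locus receives candidate genes placed uniformly within +/-500 kb
#' of the sentinel, one of which is the true causal gene. Seven of the
#' eight predictors fire independently: with probability
#' `predictor_sensitivity[p]` for the true gene and `1 -
#' predictor_specificity[p]` for every other gene. The nearest-gene
#' predictor is deterministic from the simulated gene coordinates.
#'
#' @param loci either an integer number of loci to fabricate, or a
#'   data.frame with columns `locus_id`, `chrom`, `sentinel_pos`.
#' @param truth a `truth_record` (carried through; the true-gene map is
#'   added to the return value, not stored in the matrix).
#' @param config a [sim_config()].
#' @param genes_per_locus mean number of candidate genes (minimum 3;
#'   actual counts are `3 + rpois(mean - 3)`).
#' @param window_bp half-width of the gene window around the sentinel.
#' @return a list with `matrix` (data.frame: `LOCUS_ID`, `GENE`,
#'   `DISTANCE_BP`, then the eight binary predictor columns) and
#'   `truth_genes` (data.frame `locus_id`, `gene`).
#' @export
simulate_evidence_matrix <- function(loci, truth, config,
                                     genes_per_locus = 6,
                                     window_bp = 500000L) {
  validate_sim_config(config)
  if (is.numeric(loci) && length(loci) == 1) {
    loci <- data.frame(locus_id = sprintf("locus%03d", seq_len(loci)),
                       chrom = rep_len(1:22, loci),
                       sentinel_pos = 1e6 + seq_len(loci) * 1e5)
  }
  if (nrow(loci) < 1) stop_input("at least one locus is required")
  sens <- config$predictor_sensitivity
  spec <- config$predictor_specificity
  with_substream(config$seed, "evidence_matrix", {
    rows <- list()
    truth_genes <- data.frame(locus_id = loci$locus_id,
                              gene = NA_character_,
                              stringsAsFactors = FALSE)
    for (i in seq_len(nrow(loci))) {
      ng <- 3L + stats::rpois(1, max(0, genes_per_locus - 3))
      if (ng < 1) stop_input("locus with zero candidate genes")
      offsets <- as.integer(stats::runif(ng, -window_bp, window_bp))
      genes <- sprintf("%s_G%02d", loci$locus_id[i], seq_len(ng))
      causal <- sample.int(ng, 1)
      truth_genes$gene[i] <- genes[causal]
      ev <- matrix(0L, ng, 8, dimnames = list(NULL, PREDICTORS))
      for (p in 1:7) {
        pr <- ifelse(seq_len(ng) == causal, sens[p], 1 - spec[p])
        ev[, p] <- as.integer(stats::runif(ng) < pr)
      }
      ev[, "nearest_gene"] <- as.integer(
        seq_len(ng) == which.min(abs(offsets)))
      rows[[i]] <- data.frame(
        LOCUS_ID = loci$locus_id[i],
        GENE = genes,
        DISTANCE_BP = abs(offsets),
        ev,
        stringsAsFactors = FALSE
      )
    }
    list(matrix = do.call(rbind, rows), truth_genes = truth_genes)
  })
}

#' Construct a polygenic-score model
#'
#' @param variants data.frame with columns `rsid`, `ea`, `weight` (or a
#'   three-column data.frame in that order).
#' @return object of class `prs_model`.
#' @export
prs_model <- function(variants) {
  stopifnot(is.data.frame(variants))
  if (!all(c("rsid", "ea", "weight") %in% names(variants))) {
    names(variants)[1:3] <- c("rsid", "ea", "weight")
  }
  if (anyDuplicated(variants$rsid)) stop_input("duplicate variant ids")
  if (any(!is.finite(variants$weight))) stop_input("weights must be finite")
  structure(list(variants = variants), class = "prs_model")
}

#' Simulate a prospective cohort for polygenic-score evaluation
#'
#' Dosages for the score variants are drawn binomially from the panel
#' allele frequencies (independently across variants), a standardized
#' score is formed, and binary events follow a logistic model whose
#' intercept is calibrated so that the marginal event rate matches the
#' baseline risk K. Event times for cases are uniform over follow-up;
#' non-events are censored at end of follow-up. Age, sex and five
#' principal components are included as null covariates.
#'
#' @param truth a `truth_record` (unused when `score_effect` is given
#'   explicitly; retained so the generator signature mirrors the rest of
#'   the module).
#' @param model a [prs_model()].
#' @param config a [sim_config()]; uses `cohort_n`, `baseline_risk`,
#'   `followup_years`.
#' @param panel an [ld_panel()] providing allele frequencies for the
#'   model variants.
#' @param score_effect per-1-SD log-odds of the standardized score on the
#'   event (default `log(1.6)`).
#' @return data.frame with `id`, one dosage column per score variant,
#'   `event`, `time`, `age`, `sex`, `pc1`..`pc5`.
#' @export
simulate_cohort <- function(truth, model, config, panel,
                            score_effect = log(1.6)) {
  validate_sim_config(config)
  n <- config$cohort_n
  if (n < 1) stop_input("cohort_n must be positive (empty cohort)")
  mv <- model$variants
  pv <- panel$variants
  idx <- match(mv$rsid, pv$rsid)
  if (anyNA(idx)) stop_input("model variants missing from panel: %s",
                             paste(mv$rsid[is.na(idx)], collapse = ", "))
  with_substream(config$seed, "cohort", {
    eaf <- pv$eaf[idx]
    # align simulated dosages to the model's effect allele
    flip <- mv$ea != pv$ea[idx]
    dos <- vapply(seq_along(idx), function(j) {
      d <- stats::rbinom(n, 2, eaf[j])
      if (flip[j]) 2 - d else d
    }, numeric(n))
    colnames(dos) <- mv$rsid
    raw <- drop(dos %*% mv$weight)
    s <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw
    K <- config$baseline_risk
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + score_effect * s)) - K,
      interval = c(-30, 30))$root
    event <- as.integer(stats::runif(n) <
                          stats::plogis(alpha + score_effect * s))
    time <- ifelse(event == 1,
                   stats::runif(n, 0, config$followup_years),
                   config$followup_years)
    data.frame(
      id = sprintf("ind%06d", seq_len(n)),
      dos,
      event = event,
      time = time,
      age = stats::rnorm(n, 60, 8),
      sex = stats::rbinom(n, 1, 0.5),
      pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
      pc4 = stats::rnorm(n), pc5 = stats::rnorm(n),
      check.names = FALSE,
      stringsAsFactors = FALSE
    )
  })
}
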