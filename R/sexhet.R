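#' Between-sex heterogeneity test for stratified effect estimates
#'
#' Tests equality of male and female effects (both aligned to one effect
#' allele) with `z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)` and a
#' two-sided normal p-value. A variant is flagged when it is genome-wide
#' significant in at least one stratum and the heterogeneity p-value is
#' at most `het_alpha`.
#'
#' @param beta_m,se_m,beta_f,se_f numeric vectors of stratum estimates.
#' @param gw_threshold stratum-level genome-wide significance threshold
#'   (default 5e-8).
#' @param het_alpha heterogeneity significance level (default 0.01).
#' @return data.frame with `z`, `p`, `p_m`, `p_f`, `flagged`.
#' @export
#' @examples
#' sex_heterogeneity(0.05, 0.01, 0.02, 0.01)$p  # ~0.0339
sex_heterogeneity <- function(beta_m, se_m, beta_f, se_f,
                              gw_threshold = 5e-8, het_alpha = 0.01) {
  if (any(se_m <= 0) || any(se_f <= 0)) {
    stop_input("standard errors must be positive")
  }
  z <- (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)
  p <- p_from_z(z)
  p_m <- p_from_z(beta_m / se_m)
  p_f <- p_from_z(beta_f / se_f)
  data.frame(z = z, p = p, p_m = p_m, p_f = p_f,
             flagged = (p_m <= gw_threshold | p_f <= gw_threshold) &
               p <= het_alpha)
}

#' Compare sentinel effects and frequencies between two ancestries
#'
#' Joins two meta-analysis tables on the given sentinel variant ids,
#' aligns table B to table A's effect alleles (swapped pairs are flipped),
#' and reports Pearson correlations of the aligned betas and effect
#' allele frequencies, plus the beta correlation recomputed after
#' excluding caller-specified outlier variants.
#'
#' @param tab_a,tab_b meta-analysis data.frames (columns `RSID`, `EA`,
#'   `NEA`, `BETA`, `EAF`).
#' @param sentinels character vector of sentinel RSIDs to compare.
#' @param exclude_outliers RSIDs excluded from the re-estimated beta
#'   correlation (default none).
#' @return list with `n` (overlapping sentinels), `r_beta`, `r_eaf`,
#'   `r_beta_excluding_outliers`, `excluded`.
#' @export
cross_ancestry_compare <- function(tab_a, tab_b, sentinels,
                                   exclude_outliers = character(0)) {
  ids <- intersect(sentinels, intersect(tab_a$RSID, tab_b$RSID))
  if (length(ids) < 3) {
    stop_input("fewer than 3 overlapping sentinels (%d)", length(ids))
  }
  ia <- match(ids, tab_a$RSID)
  ib <- match(ids, tab_b$RSID)
  same <- tab_b$EA[ib] == tab_a$EA[ia] & tab_b$NEA[ib] == tab_a$NEA[ia]
  swap <- tab_b$EA[ib] == tab_a$NEA[ia] & tab_b$NEA[ib] == tab_a$EA[ia]
  if (any(!same & !swap)) {
    stop_input("incompatible alleles at sentinel %s",
               ids[which(!same & !swap)[1]])
  }
  beta_b <- ifelse(swap, -tab_b$BETA[ib], tab_b$BETA[ib])
  eaf_b <- ifelse(swap, 1 - tab_b$EAF[ib], tab_b$EAF[ib])
  keep <- !(ids %in% exclude_outliers)
  list(
    n = length(ids),
    r_beta = stats::cor(tab_a$BETA[ia], beta_b),
    r_eaf = stats::cor(tab_a$EAF[ia], eaf_b),
    r_beta_excluding_outliers = if (sum(keep) >= 3) {
      stats::cor(tab_a$BETA[ia][keep], beta_b[keep])
    } else {
      NA_real_
    },
    excluded = ids[!keep]
  )
}
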