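# Per-study summary statistics under the standard summary-statistic
# asymptotics for case-control log-odds: marginal effects are the
# LD-projection of the joint effects (in standardized genotype units),
# and the sampling noise has covariance sigma^2 R / N_eff with
# N_eff = 4 / (1/N_cases + 1/N_controls) and sigma^2 = 4, which
# reproduces the familiar var(beta_j) = (1/N_cases + 1/N_controls) /
# (2 p_j (1 - p_j)).

#' Effective sample size of a case-control study
#'
#' @param n_cases,n_controls case and control counts.
#' @return `4 / (1/n_cases + 1/n_controls)`.
#' @export
effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

#' Simulate per-study GWAS summary-statistic tables
#'
#' Marginal per-allele effects are computed by projecting the true joint
#' effects through the LD matrix in standardized genotype units
#' (`u_marg = R u_joint`), then correlated sampling noise is added per
#' study. A random fraction of rows in each study is stored on the other
#' allele (effect/non-effect swapped, beta negated, frequency
#' complemented) so that allele-alignment code is exercised.
#'
#' @param panel an [ld_panel()].
#' @param truth a `truth_record` from [simulate_truth()].
#' @param config a [sim_config()].
#' @param ancestry `"primary"` uses `truth$beta`; `"secondary"` uses
#'   `truth$beta_ancestry2`.
#' @param n_studies optional override of `config$n_studies`.
#' @param flip_fraction fraction of rows emitted on the opposite allele.
#' @return named list of data.frames, one per study, with columns
#'   `CHR, POS, RSID, EA, NEA, EAF, BETA, SE, P, N_CASES, N_CONTROLS, INFO`.
#' @export
simulate_summary_stats <- function(panel, truth, config,
                                   ancestry = c("primary", "secondary"),
                                   n_studies = NULL,
                                   flip_fraction = 0.2) {
  ancestry <- match.arg(ancestry)
  if (!identical(truth$causal_rsid,
                 panel$variants$rsid[truth$causal_index])) {
    stop_input("truth record does not match the supplied panel")
  }
  b_joint <- if (ancestry == "primary") truth$beta else truth$beta_ancestry2
  if (length(b_joint) != nrow(panel$variants)) {
    stop_input("truth effect vector length does not match panel")
  }
  ns <- n_studies %||% config$n_studies
  cases <- rep_len(config$per_study_cases, ns)
  controls <- rep_len(config$per_study_controls, ns)
  v <- panel$variants
  m <- nrow(v)
  D <- 2 * v$eaf * (1 - v$eaf)
  sqD <- sqrt(D)
  u_marg <- drop(panel$R %*% (sqD * b_joint))
  b_marg <- u_marg / sqD
  # per-block Cholesky factors for correlated noise
  blocks <- split(seq_len(m), v$block %||% rep(1L, m))
  chols <- lapply(blocks, function(idx) chol(panel$R[idx, idx, drop = FALSE]))
  sigma2 <- 4
  with_substream(config$seed, paste0("summary_stats_", ancestry), {
    out <- vector("list", ns)
    for (s in seq_len(ns)) {
      neff <- effective_n(cases[s], controls[s])
      eps_std <- numeric(m)
      for (k in seq_along(blocks)) {
        idx <- blocks[[k]]
        z <- stats::rnorm(length(idx))
        eps_std[idx] <- drop(crossprod(chols[[k]], z))
      }
      beta <- b_marg + eps_std * sqrt(sigma2 / neff) / sqD
      se <- sqrt(sigma2 / (neff * D))
      zsc <- beta / se
      eaf <- pmin(pmax(v$eaf + stats::rnorm(m, 0, sqrt(v$eaf * (1 - v$eaf) /
                                                         (2 * neff))),
                       0.001), 0.999)
      tab <- data.frame(
        CHR = v$chrom, POS = v$pos, RSID = v$rsid,
        EA = v$ea, NEA = v$nea, EAF = eaf,
        BETA = beta, SE = se, P = p_from_z(zsc),
        N_CASES = cases[s], N_CONTROLS = controls[s],
        INFO = stats::runif(m, 0.9, 1),
        stringsAsFactors = FALSE
      )
      flip <- stats::runif(m) < flip_fraction
      if (any(flip)) {
        tmp <- tab$EA[flip]
        tab$EA[flip] <- tab$NEA[flip]
        tab$NEA[flip] <- tmp
        tab$BETA[flip] <- -tab$BETA[flip]
        tab$EAF[flip] <- 1 - tab$EAF[flip]
      }
      out[[s]] <- tab
    }
    names(out) <- sprintf("study%02d", seq_len(ns))
    out
  })
}

#' Simulate binary functional-annotation tracks
#'
#' Emulates merged likely-functional chromatin states per tissue: each
#' tissue annotates a background fraction of variants, and for enriched
#' tissues the odds of annotation at causal variants equal the configured
#' fold times the background odds, so the expected causal/non-causal
#' annotation odds ratio is the configured fold.
#'
#' @param panel an [ld_panel()].
#' @param truth a `truth_record`.
#' @param config a [sim_config()]; uses `annotation_enrichment` (fold per
#'   tissue, >= 1) and `annotation_coverage`.
#' @return an integer matrix `n_variants x n_tissues` of 0/1 annotations
#'   with tissues as column names, class `annotation_set`.
#' @export
simulate_annotations <- function(panel, truth, config) {
  validate_sim_config(config)
  m <- nrow(panel$variants)
  is_causal <- seq_len(m) %in% truth$causal_index
  with_substream(config$seed, "annotations", {
    A <- matrix(0L, m, config$n_tissues,
                dimnames = list(panel$variants$rsid,
                                sprintf("tissue%02d",
                                        seq_len(config$n_tissues))))
    for (t in seq_len(config$n_tissues)) {
      cov <- config$annotation_coverage[t]
      fold <- config$annotation_enrichment[t]
      if (cov == 0) next  # empty track; enrichment is non-identifiable
      odds0 <- cov / (1 - cov)
      p_causal <- fold * odds0 / (1 + fold * odds0)
      pr <- ifelse(is_causal, p_causal, cov)
      A[, t] <- as.integer(stats::runif(m) < pr)
    }
    class(A) <- c("annotation_set", class(A))
    A
  })
}

#' Write annotation tracks as BED (0-based half-open) files
#'
#' @param annotations an `annotation_set` matrix.
#' @param panel the [ld_panel()] the annotations were generated on.
#' @param dir output directory; one `<tissue>.bed` file per tissue.
#' @return invisibly, the paths written.
#' @export
write_annotation_bed <- function(annotations, panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- panel$variants
  paths <- character(0)
  for (t in colnames(annotations)) {
    idx <- which(annotations[, t] == 1L)
    bed <- data.frame(chrom = paste0("chr", v$chrom[idx]),
                      start = v$pos[idx] - 1L,  # 1-based pos -> 0-based bed
                      end = v$pos[idx],
                      name = v$rsid[idx])
    path <- file.path(dir, paste0(t, ".bed"))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a BED track (0-based half-open) onto a panel's variants
#'
#' @param path BED file path.
#' @param panel an [ld_panel()].
#' @return integer 0/1 vector over the panel's variants.
#' @export
read_annotation_bed <- function(path, panel) {
  v <- panel$variants
  out <- integer(nrow(v))
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  chrom <- sub("^chr", "", bed$chrom)
  for (i in seq_len(nrow(bed))) {
    hit <- v$chrom == chrom[i] & v$pos > bed$start[i] & v$pos <= bed$end[i]
    out[hit] <- 1L
  }
  out
}
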