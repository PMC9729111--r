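#' Construct an LD panel object
#'
#' An LD panel couples an ordered variant table with a correlation matrix
#' and serves both r-squared queries (clumping, novelty, proxies) and the
#' approximate conditional analysis.
#'
#' @param variants data.frame with columns `rsid`, `chrom`, `pos`, `ea`,
#'   `nea`, `eaf` (and optionally `block`).
#' @param R square correlation matrix, rows/cols in variant order.
#' @param tol tolerance for the symmetry / unit-diagonal / PSD checks.
#' @return an object of class `ld_panel`.
#' @export
ld_panel <- function(variants, R, tol = 1e-8) {
  stopifnot(is.data.frame(variants), is.matrix(R))
  if (nrow(variants) != nrow(R) || nrow(R) != ncol(R)) {
    stop_input("variant table and correlation matrix dimensions disagree")
  }
  if (max(abs(R - t(R))) > tol) stop_input("LD matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > tol) stop_input("LD matrix diagonal is not 1")
  if (max(abs(R)) > 1 + tol) stop_input("LD entries must satisfy |r| <= 1")
  dimnames(R) <- list(variants$rsid, variants$rsid)
  structure(list(variants = variants, R = R), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d variants, %d block(s)\n",
              nrow(x$variants),
              length(unique(x$variants$block %||% 1L))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a block-diagonal AR(1) LD panel
#'
#' Variants are laid out in `n_blocks` blocks. Within a block the
#' correlation between variants i and j is `block_rho^|i-j|` (AR(1)),
#' between blocks it is exactly zero, so the matrix is symmetric
#' positive-semidefinite by construction. Blocks are placed 10 Mb apart
#' along chromosomes so physical distance and LD structure agree. Allele
#' frequencies are drawn uniformly in `[0.01, 0.5]` and alleles are
#' assigned at random so downstream alignment code is exercised.
#'
#' @param config a [sim_config()] object.
#' @return an [ld_panel()] whose `variants` carry a `block` column.
#' @export
#' @examples
#' panel <- simulate_ld_panel(sim_config(seed = 1, n_variants = 60,
#'                                       n_blocks = 6))
#' dim(panel$R)
simulate_ld_panel <- function(config) {
  validate_sim_config(config)
  m <- config$n_variants
  nb <- config$n_blocks
  rho <- config$block_rho
  if (m < nb) stop_input("n_variants must be >= n_blocks")
  with_substream(config$seed, "ld_panel", {
    block <- sort(rep_len(seq_len(nb), m))
    block_sizes <- tabulate(block, nb)
    # chromosome/position layout: blocks 2 Mb apart (beyond any clumping
    # window), variants 5 kb apart; positions kept numeric since many
    # blocks on one chromosome can exceed the integer range
    chrom_of_block <- ((seq_len(nb) - 1L) %% 22L) + 1L
    idx_on_chrom <- stats::ave(seq_len(nb), chrom_of_block,
                               FUN = seq_along)
    spacing <- max(block_sizes) * 5000 + 2e6
    block_start <- 1e6 + (idx_on_chrom - 1) * spacing
    within <- unlist(lapply(block_sizes, seq_len), use.names = FALSE)
    pos <- block_start[block] + (within - 1) * 5000
    chrom <- chrom_of_block[block]
    alle <- t(vapply(seq_len(m),
                     function(i) sample(c("A", "C", "G", "T"), 2),
                     character(2)))
    variants <- data.frame(
      rsid = sprintf("rs%07d", seq_len(m)),
      chrom = chrom,
      pos = pos,
      ea = alle[, 1],
      nea = alle[, 2],
      eaf = stats::runif(m, 0.01, 0.5),
      block = block,
      stringsAsFactors = FALSE
    )
    R <- matrix(0, m, m)
    off <- 0L
    for (b in seq_len(nb)) {
      k <- block_sizes[b]
      idx <- off + seq_len(k)
      R[idx, idx] <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
      off <- off + k
    }
    ld_panel(variants, R)
  })
}

#' True generative state of a synthetic GWAS world
#'
#' Samples causal variants and their per-allele log-odds effects in the
#' primary ancestry, plus a correlated effect vector for a second ancestry
#' with correlation `cross_ancestry_r`. Truth is emitted alongside the
#' data, never inside the data files.
#'
#' @param panel an [ld_panel()].
#' @param config a [sim_config()].
#' @return an object of class `truth_record` with elements
#'   `causal_rsid`, `beta` (full-length joint effect vector, primary
#'   ancestry), `beta_ancestry2`, `log_enrichment` (per tissue) and
#'   `cross_ancestry_r`.
#' @export
simulate_truth <- function(panel, config) {
  validate_sim_config(config)
  m <- nrow(panel$variants)
  if (config$n_causal > m) stop_input("more causal variants than panel size")
  with_substream(config$seed, "truth", {
    causal <- sort(sample.int(m, config$n_causal))
    b <- numeric(m)
    b2 <- numeric(m)
    r <- config$cross_ancestry_r
    sd <- config$causal_beta_sd
    b[causal] <- stats::rnorm(config$n_causal, 0, sd)
    b2[causal] <- r * b[causal] +
      sqrt(max(0, 1 - r^2)) * stats::rnorm(config$n_causal, 0, sd)
    structure(list(
      causal_rsid = panel$variants$rsid[causal],
      causal_index = causal,
      beta = b,
      beta_ancestry2 = b2,
      log_enrichment = log(config$annotation_enrichment),
      cross_ancestry_r = r
    ), class = "truth_record")
  })
}
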