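# Shared fixture builders. Everything is generated in code at test time;
# no stored fixtures.

# A small complete synthetic world reused by several test files.
small_world <- function(seed = 1, n_variants = 200, n_blocks = 20,
                        n_causal = 5, ...) {
  cfg <- sim_config(seed = seed, n_variants = n_variants,
                    n_blocks = n_blocks, n_causal = n_causal, ...)
  panel <- simulate_ld_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  list(cfg = cfg, panel = panel, truth = truth)
}

# Single-causal fine-mapping regions on the z-score scale: the causal
# variant is drawn from the annotation-weighted prior (pi ~ exp(gamma a))
# and its standardized effect from N(0, Wz), so Wakefield ABFs with
# prior variance Wz are the exactly matched single-causal model.
make_finemap_regions <- function(n_regions, m = 40, rho = 0.9,
                                 gamma = log(5), coverage = 0.2,
                                 Wz = 25, seed = 1) {
  set.seed(seed)
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  L <- chol(R)
  regions <- vector("list", n_regions)
  causal <- character(n_regions)
  for (i in seq_len(n_regions)) {
    a <- stats::rbinom(m, 1, coverage)
    pri <- exp(gamma * a)
    cc <- sample.int(m, 1, prob = pri / sum(pri))
    lam <- stats::rnorm(1, 0, sqrt(Wz))
    z <- drop(R[, cc] * lam + crossprod(L, stats::rnorm(m)))
    rsid <- sprintf("r%03d_v%02d", i, seq_len(m))
    regions[[i]] <- list(
      id = sprintf("region%03d", i),
      chrom = 1L, start = 1L, end = m,
      variants = data.frame(RSID = rsid, BETA = z, SE = 1,
                            P = p_from_z(z), stringsAsFactors = FALSE),
      annotations = matrix(a, m, 1, dimnames = list(rsid, "t1"))
    )
    causal[i] <- rsid[cc]
  }
  list(regions = regions, causal = causal)
}

# Identity-LD panel helper (every variant its own block).
identity_world <- function(seed, n_variants, n_causal = 0, ...) {
  small_world(seed = seed, n_variants = n_variants,
              n_blocks = n_variants, n_causal = n_causal, ...)
}

# Hand-buildable evidence matrix row helper.
ev_row <- function(locus, gene, dist, marks = character(0)) {
  r <- data.frame(LOCUS_ID = locus, GENE = gene, DISTANCE_BP = dist,
                  stringsAsFactors = FALSE)
  for (p in cadgwas:::PREDICTORS) r[[p]] <- as.integer(p %in% marks)
  r
}
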