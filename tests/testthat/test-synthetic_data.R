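test_that("LD panel has the stated block-AR(1) structure", {
  cfg <- sim_config(seed = 3, n_variants = 30, n_blocks = 3,
                    block_rho = 0.9)
  panel <- simulate_ld_panel(cfg)
  # AR(1) closed form within a block: corr(1,3) = rho^2
  expect_equal(panel$R[1, 3], 0.81)
  expect_equal(panel$R[1, 2], 0.9)
  # zero between blocks
  expect_equal(panel$R[1, 11], 0)
  # rho = 0 gives the identity
  id <- simulate_ld_panel(sim_config(seed = 3, n_variants = 12,
                                     n_blocks = 3, block_rho = 0))
  expect_equal(id$R, diag(12), ignore_attr = TRUE)
  # eigendecomposition oracle: PSD within tolerance
  expect_gte(min(eigen(panel$R, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  expect_true(all(panel$variants$eaf >= 0.01 & panel$variants$eaf <= 0.5))
})

test_that("LD panel rejects bad configurations", {
  expect_error(sim_config(n_variants = 0), "positive")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(n_causal = 10, n_variants = 5), "exceeds")
})

test_that("identical config produces byte-identical outputs", {
  w1 <- small_world(seed = 11)
  w2 <- small_world(seed = 11)
  expect_identical(w1$panel, w2$panel)
  expect_identical(w1$truth, w2$truth)
  s1 <- simulate_summary_stats(w1$panel, w1$truth, w1$cfg)
  s2 <- simulate_summary_stats(w2$panel, w2$truth, w2$cfg)
  expect_identical(s1, s2)
  # sub-streams: generating annotations first does not change stats
  invisible(simulate_annotations(w2$panel, w2$truth, w2$cfg))
  s3 <- simulate_summary_stats(w2$panel, w2$truth, w2$cfg)
  expect_identical(s1, s3)
})

test_that("null summary statistics are calibrated", {
  w <- identity_world(seed = 5, n_variants = 5000)
  st <- simulate_summary_stats(w$panel, w$truth, w$cfg, n_studies = 1)
  z <- st[[1]]$BETA / st[[1]]$SE
  # independent variants (identity LD): Z should be standard normal
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
  # genome-wide significant count near binomial expectation
  expect_lte(sum(st[[1]]$P < 5e-8), 2)
})

test_that("marginal effects are the LD projection of joint effects", {
  # two variants, r = 0.5, equal frequencies: b_joint = (0.2, 0)
  # projects to E[b_marg] = (0.2, 0.1)
  v <- data.frame(rsid = c("v1", "v2"), chrom = 1, pos = c(100, 200),
                  ea = "A", nea = "G", eaf = 0.3, block = 1L)
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  panel <- ld_panel(v, R)
  truth <- structure(list(causal_rsid = "v1", causal_index = 1L,
                          beta = c(0.2, 0), beta_ancestry2 = c(0.2, 0),
                          log_enrichment = 0, cross_ancestry_r = 1),
                     class = "truth_record")
  cfg <- sim_config(seed = 1, n_variants = 2, n_blocks = 1, n_causal = 1,
                    per_study_cases = 5e5, per_study_controls = 5e5)
  reps <- vapply(1:60, function(s) {
    cfg$seed <- s
    st <- simulate_summary_stats(panel, truth, cfg, n_studies = 1,
                                 flip_fraction = 0)
    st[[1]]$BETA
  }, numeric(2))
  expect_equal(rowMeans(reps), c(0.2, 0.1), tolerance = 0.02)
})

test_that("single causal variant under identity LD gains |Z| with N", {
  grow <- vapply(c(2e4, 2e5), function(n) {
    w <- identity_world(seed = 9, n_variants = 50, n_causal = 1,
                        per_study_cases = n, per_study_controls = n,
                        causal_beta_sd = 0.1)
    st <- simulate_summary_stats(w$panel, w$truth, w$cfg, n_studies = 1,
                                 flip_fraction = 0)
    z <- abs(st[[1]]$BETA / st[[1]]$SE)
    c(z[w$truth$causal_index], max(z[-w$truth$causal_index]))
  }, numeric(2))
  expect_gt(grow[1, 2], grow[1, 1])        # causal |Z| grows with N
  expect_lt(grow[2, 2], grow[1, 2] / 2)    # null variants do not
})

test_that("truth/panel mismatch is an input error", {
  w <- small_world(seed = 2)
  other <- small_world(seed = 2, n_variants = 100, n_blocks = 10)
  expect_error(simulate_summary_stats(other$panel, w$truth, w$cfg),
               "match")
})

test_that("annotation enrichment hits the configured odds ratio", {
  cfg <- sim_config(seed = 21, n_variants = 10000, n_blocks = 10000,
                    n_causal = 200, annotation_enrichment = c(5, 1),
                    annotation_coverage = 0.1, n_tissues = 2)
  panel <- simulate_ld_panel(cfg)
  truth <- simulate_truth(panel, cfg)
  ann <- simulate_annotations(panel, truth, cfg)
  is_causal <- seq_len(10000) %in% truth$causal_index
  or_of <- function(a) {
    tab <- table(factor(a, 0:1), factor(is_causal, c(FALSE, TRUE)))
    (tab[2, 2] / tab[1, 2]) / (tab[2, 1] / tab[1, 1])
  }
  # binomial sampling oracle band for fold = 5 at this size
  expect_gt(or_of(ann[, 1]), 3.5)
  expect_lt(or_of(ann[, 1]), 7)
  # fold = 1: annotation independent of causal status
  p <- stats::chisq.test(table(ann[, 2], is_causal))$p.value
  expect_gt(p, 0.001)
})

test_that("zero-coverage annotation track is empty and flagged downstream", {
  w <- small_world(seed = 4, annotation_coverage = 0,
                   annotation_enrichment = rep(1, 10))
  ann <- simulate_annotations(w$panel, w$truth, w$cfg)
  expect_true(all(ann == 0))
  region <- list(id = "r1", variants = data.frame(
    RSID = w$panel$variants$rsid[1:10], BETA = 0.1, SE = 0.05, P = 0.04),
    annotations = ann[1:10, , drop = FALSE])
  expect_error(fit_enrichment(list(region), "tissue01"),
               "not identifiable")
})

test_that("evidence generator respects sensitivity/specificity", {
  # perfect predictors: consensus recovers truth at 100% of loci
  w <- small_world(seed = 6, predictor_sensitivity = rep(1, 8),
                   predictor_specificity = rep(1, 8))
  ev <- simulate_evidence_matrix(30L, w$truth, w$cfg)
  res <- prioritize_all(ev$matrix)
  ok <- mapply(function(noms, truth_gene) truth_gene %in% noms,
               res$nominees[match(ev$truth_genes$locus_id, res$locus_id)],
               ev$truth_genes$gene)
  expect_true(all(ok))
  # sensitivity 0, specificity 1: only the deterministic nearest-gene
  # predictor fires, so no locus reaches the two-predictor threshold
  w0 <- small_world(seed = 6, predictor_sensitivity = rep(0, 8),
                    predictor_specificity = rep(1, 8))
  ev0 <- simulate_evidence_matrix(30L, w0$truth, w0$cfg)
  res0 <- prioritize_all(ev0$matrix)
  expect_true(all(res0$n_concordant <= 1))
  expect_true(all(res0$tier == "none"))
  # sens 0.8 / spec 0.95 at 100 loci: per-predictor hit rate for the
  # true gene within the binomial 95% CI of 0.8 (counting oracle)
  w8 <- small_world(seed = 8)
  ev8 <- simulate_evidence_matrix(100L, w8$truth, w8$cfg)
  half <- 1.96 * sqrt(0.8 * 0.2 / 100)
  for (p in cadgwas:::PREDICTORS[1:7]) {
    hits <- mapply(function(l, g) {
      any(ev8$matrix$LOCUS_ID == l & ev8$matrix$GENE == g &
            ev8$matrix[[p]] == 1)
    }, ev8$truth_genes$locus_id, ev8$truth_genes$gene)
    expect_gt(mean(hits), 0.8 - 1.5 * half)
    expect_lt(mean(hits), 0.8 + 1.5 * half)
  }
  # nearest gene marks exactly one gene per locus
  ng <- tapply(ev8$matrix$nearest_gene, ev8$matrix$LOCUS_ID, sum)
  expect_true(all(ng == 1))
})

test_that("cohort generator honours dosage bounds and degenerate input", {
  w <- small_world(seed = 10, cohort_n = 500)
  model <- prs_model(data.frame(
    rsid = w$truth$causal_rsid,
    ea = w$panel$variants$ea[w$truth$causal_index],
    weight = w$truth$beta[w$truth$causal_index]))
  cohort <- simulate_cohort(w$truth, model, w$cfg, w$panel)
  dos <- as.matrix(cohort[, model$variants$rsid])
  expect_true(all(dos >= 0 & dos <= 2))
  expect_true(all(cohort$time > 0 & cohort$time <= w$cfg$followup_years))
  expect_error(
    simulate_cohort(w$truth, model,
                    sim_config(seed = 1, cohort_n = 0), w$panel),
    "cohort_n")
})

test_that("zero score effect gives flat decile event rates", {
  w <- small_world(seed = 12, cohort_n = 4000)
  model <- prs_model(data.frame(
    rsid = w$truth$causal_rsid,
    ea = w$panel$variants$ea[w$truth$causal_index],
    weight = w$truth$beta[w$truth$causal_index]))
  ratios <- vapply(1:20, function(s) {
    cfg <- w$cfg; cfg$seed <- s
    cohort <- simulate_cohort(w$truth, model, cfg, w$panel,
                              score_effect = 0)
    sc <- prs_score(cohort, model)
    decile_stratify(sc, cohort$event)$top_vs_bottom
  }, numeric(1))
  expect_equal(mean(ratios[is.finite(ratios)]), 1, tolerance = 0.25)
})
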