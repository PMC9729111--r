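test_that("allele alignment flips, complements and drops as declared", {
  a <- list(ea = "A", nea = "G", beta = 0.1, eaf = 0.3)
  # identical alleles: unchanged
  r <- align_alleles(a, list(ea = "A", nea = "G", beta = 0.05, eaf = 0.3))
  expect_equal(r$b$beta, 0.05)
  expect_false(r$flipped)
  # swapped alleles: sign and frequency flip
  r <- align_alleles(a, list(ea = "G", nea = "A", beta = 0.05, eaf = 0.3))
  expect_equal(r$b$beta, -0.05)
  expect_equal(r$b$eaf, 0.7)
  # strand complement (A/G vs T/C)
  r <- align_alleles(a, list(ea = "T", nea = "C", beta = 0.05, eaf = 0.3))
  expect_equal(r$b$beta, 0.05)
  # palindromic near 0.5: dropped with warning under default policy
  pal_a <- list(ea = "A", nea = "T", beta = 0.1, eaf = 0.49)
  pal_b <- list(ea = "A", nea = "T", beta = 0.1, eaf = 0.49)
  expect_warning(r <- align_alleles(pal_a, pal_b), "dropped")
  expect_true(r$dropped)
  # palindromic at low MAF aligned by frequency
  lo_a <- list(ea = "A", nea = "T", beta = 0.1, eaf = 0.1)
  lo_b <- list(ea = "T", nea = "A", beta = 0.1, eaf = 0.9)
  r <- align_alleles(lo_a, lo_b)
  expect_equal(r$b$beta, -0.1)
  expect_equal(r$b$eaf, 0.1)
  # incompatible sets
  expect_error(align_alleles(a, list(ea = "C", nea = "G", beta = 0,
                                     eaf = 0.5)), "incompatible")
})

test_that("IVW pooling matches its closed form and handles extremes", {
  # equal weights
  r <- ivw_meta(c(0.1, 0.1), c(0.1, 0.1))
  expect_equal(r$beta, 0.1)
  expect_equal(r$se, 0.1 / sqrt(2))
  # hand closed form, weights (100, 25)
  r <- ivw_meta(c(0.2, 0), c(0.1, 0.2))
  expect_equal(r$beta, 0.16)
  expect_equal(r$se, sqrt(1 / 125))
  # single study: identity
  r <- ivw_meta(0.07, 0.02)
  expect_equal(r$beta, 0.07)
  expect_equal(r$se, 0.02)
  # duplicated study halves the variance
  r2 <- ivw_meta(c(0.07, 0.07), c(0.02, 0.02))
  expect_equal(r2$se, 0.02 / sqrt(2))
  # p never exactly zero even at |z| = 40 and beyond
  r <- ivw_meta(4, 0.1)
  expect_gt(r$p, 0)
  expect_lt(r$log10_p, -300)
  expect_error(ivw_meta(0.1, 0), "positive")
})

test_that("IVW equals a weighted-least-squares regression oracle", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    b <- stats::rnorm(k, 0, 0.2)
    s <- stats::runif(k, 0.01, 0.5)
    fit <- stats::lm(b ~ 1, weights = 1 / s^2)
    r <- ivw_meta(b, s)
    expect_equal(r$beta, unname(stats::coef(fit)[1]), tolerance = 1e-12)
  }
})

test_that("meta_analyze aligns swapped rows and pools across studies", {
  s1 <- data.frame(CHR = 1, POS = c(100, 200), RSID = c("v1", "v2"),
                   EA = c("A", "C"), NEA = c("G", "T"),
                   EAF = c(0.3, 0.2), BETA = c(0.1, -0.05),
                   SE = c(0.02, 0.03), P = 1, N_CASES = 1000,
                   N_CONTROLS = 4000)
  s2 <- s1
  s2$EA <- c("G", "C"); s2$NEA <- c("A", "T")
  s2$BETA <- c(-0.1, -0.05); s2$EAF <- c(0.7, 0.2)
  m <- meta_analyze(list(s1, s2))
  expect_equal(m$BETA[m$RSID == "v1"], 0.1)
  expect_equal(m$SE[m$RSID == "v1"], 0.02 / sqrt(2))
  expect_equal(m$N_STUDIES, c(2L, 2L))
  expect_equal(m$N_CASES, c(2000, 2000))
})

test_that("variant filtering applies study and case-count thresholds", {
  tab <- data.frame(RSID = sprintf("v%d", 1:6),
                    N_STUDIES = c(1, 2, 2, 3, 1, 2),
                    N_CASES = c(50000, 29999, 30000, 45000, 10000, 80000))
  out <- filter_variants(tab)
  # hand trace: v3, v4, v6 survive
  expect_equal(out$RSID, c("v3", "v4", "v6"))
  expect_equal(nrow(filter_variants(tab[0, ])), 0)
})

test_that("clumping is transitive with min-p sentinels", {
  v <- data.frame(CHR = 1, POS = c(1.0e6, 1.3e6, 2.5e6),
                  RSID = c("a", "b", "c"), P = c(1e-9, 1e-10, 1e-12))
  cl <- clump_loci(v)
  expect_equal(nrow(cl$loci), 2)
  expect_equal(cl$members[[1]], c("a", "b"))
  expect_equal(cl$loci$sentinel_rsid, c("b", "c"))
  # chaining: 1.0, 1.4, 1.8 Mb collapse into one locus
  v2 <- data.frame(CHR = 1, POS = c(1.0e6, 1.4e6, 1.8e6),
                   RSID = c("a", "b", "c"), P = c(1e-9, 1e-9, 1e-8))
  cl2 <- clump_loci(v2)
  expect_equal(nrow(cl2$loci), 1)
  expect_equal(cl2$loci$sentinel_rsid, "a")  # p tie broken by position
  # single variant: singleton locus
  expect_equal(nrow(clump_loci(v2[1, ])$loci), 1)
  # partition property on a random instance
  set.seed(33)
  v3 <- data.frame(CHR = sample(1:3, 60, TRUE),
                   POS = sample.int(1e7, 60), RSID = sprintf("s%d", 1:60),
                   P = stats::runif(60))
  cl3 <- clump_loci(v3)
  expect_setequal(unlist(cl3$members), v3$RSID)
  expect_equal(anyDuplicated(unlist(cl3$members)), 0)
})

test_that("novelty annotation honours region, r2 boundary and panel gaps", {
  v <- data.frame(rsid = c("s1", "k1", "s2", "k2"), chrom = c(1, 1, 2, 2),
                  pos = c(1e6, 1.2e6, 5e6, 5.1e6),
                  ea = "A", nea = "G", eaf = 0.2, block = c(1, 1, 2, 2))
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- sqrt(0.95)
  R[3, 4] <- R[4, 3] <- sqrt(0.2)  # r2 exactly 0.2: counts as known
  panel <- ld_panel(v, R)
  known <- data.frame(RSID = c("k1", "k2"), CHR = c(1, 2),
                      POS = c(1.2e6, 5.1e6))
  loci <- data.frame(locus_id = c("L1", "L2", "L3"), chrom = c(1, 2, 3),
                     start = c(0.9e6, 4.99e6, 9e6),
                     end = c(1.1e6, 5.01e6, 9.1e6),
                     sentinel_rsid = c("s1", "s2", "zz"),
                     sentinel_pos = c(1e6, 5e6, 9e6))
  out <- annotate_novelty(loci, known, panel)
  expect_equal(out$novelty, c("known", "known", "unassessed"))
  # far from any known variant, r2 below threshold: new
  out2 <- annotate_novelty(
    data.frame(locus_id = "L4", chrom = 1, start = 8e6, end = 8.1e6,
               sentinel_rsid = "s1", sentinel_pos = 8e6),
    known[known$RSID == "none", , drop = FALSE], panel)
  expect_equal(out2$novelty, "new")
})

test_that("q-values reproduce BH at pi0 = 1 and estimate pi0 under the null", {
  expect_equal(qvalue_fdr(rep(1, 5))$qvalues, rep(1, 5))
  q <- qvalue_fdr(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(q$qvalues, rep(0.04, 4))
  # order invariance and q <= 1
  set.seed(5)
  p <- stats::runif(300)^1.5
  q1 <- qvalue_fdr(p)$qvalues
  perm <- sample(300)
  q2 <- qvalue_fdr(p[perm])$qvalues
  expect_equal(q1[perm], q2)
  expect_true(all(q1 <= 1))
  # monotone non-decreasing in p after sorting
  expect_true(all(diff(q1[order(p)]) >= -1e-12))
  # uniform p at m = 10000: pi0 within [0.9, 1.1]
  set.seed(6)
  est <- qvalue_fdr(stats::runif(10000))$pi0
  expect_gt(est, 0.9)
  expect_lte(est, 1.1)
  # reported threshold is the largest passing p
  set.seed(7)
  p2 <- c(stats::runif(50, 0, 1e-5), stats::runif(950))
  r <- qvalue_fdr(p2, target_fdr = 0.01)
  expect_true(all(r$qvalues[p2 <= r$p_threshold] <= 0.01))
  expect_error(qvalue_fdr(numeric(0)), "empty")
})

test_that("sex heterogeneity test matches hand arithmetic and is calibrated", {
  r <- sex_heterogeneity(0.05, 0.01, 0.05, 0.01)
  expect_equal(r$p, 1)
  r <- sex_heterogeneity(0.05, 0.01, 0.02, 0.01)
  expect_equal(r$z, 0.03 / sqrt(2e-4), tolerance = 1e-10)
  expect_equal(r$z, 2.1213, tolerance = 1e-4)
  expect_equal(r$p, 0.0339, tolerance = 1e-3)
  expect_error(sex_heterogeneity(0.1, 0, 0.1, 0.01), "positive")
  # null calibration: equal true effects, p uniform
  set.seed(8)
  bm <- stats::rnorm(1000, 0.05, 0.01)
  bf <- stats::rnorm(1000, 0.05, 0.01)
  p <- sex_heterogeneity(bm, 0.01, bf, 0.01)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("cross-ancestry comparison aligns and correlates sentinels", {
  mk <- function(beta, eaf, ea = "A", nea = "G") {
    data.frame(RSID = sprintf("v%d", seq_along(beta)), EA = ea, NEA = nea,
               BETA = beta, EAF = eaf, stringsAsFactors = FALSE)
  }
  a <- mk(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(cross_ancestry_compare(a, a, a$RSID)$r_beta, 1)
  b <- mk(c(0.3, 0.2, 0.1), c(0.3, 0.2, 0.1))
  expect_equal(cross_ancestry_compare(a, b, a$RSID)$r_beta, -1)
  # allele-swapped copy still correlates +1 after alignment
  b2 <- mk(-c(0.1, 0.2, 0.3), 1 - c(0.1, 0.2, 0.3), ea = "G", nea = "A")
  r <- cross_ancestry_compare(a, b2, a$RSID)
  expect_equal(r$r_beta, 1)
  expect_equal(r$r_eaf, 1)
  expect_error(cross_ancestry_compare(a[1:2, ], a[1:2, ], a$RSID[1:2]),
               "fewer than 3")
  # outlier exclusion is honoured
  a4 <- mk(c(0.1, 0.2, 0.3, 5), c(0.1, 0.2, 0.3, 0.4))
  b4 <- mk(c(0.1, 0.2, 0.3, -5), c(0.1, 0.2, 0.3, 0.4))
  r4 <- cross_ancestry_compare(a4, b4, a4$RSID, exclude_outliers = "v4")
  expect_lt(r4$r_beta, 0)
  expect_equal(r4$r_beta_excluding_outliers, 1)
  expect_equal(r4$excluded, "v4")
})
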