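# cadgwas

Tools for everything that happens *after* a large case-control GWAS
meta-analysis of a complex disease such as coronary artery disease: the
post-GWAS analytical chain from pooled summary statistics to prioritized
causal genes and polygenic risk stratification. The intended user is a
statistical geneticist who has per-study summary statistics, an LD
reference panel, functional annotation tracks, per-locus gene evidence,
and PRS weights — and wants a tested, scriptable implementation of each
downstream step without assembling five separate tools.

Every input format the pipeline consumes can also be *generated* by the
built-in synthetic-data module, with the statistical structure the
analyses assume (polygenic liability architecture, block LD, enriched
annotations, two correlated ancestries, eight noisy gene predictors, a
prospective cohort), so the entire chain is testable end-to-end with no
external download.

## What it computes

- **Meta-analysis** — fixed-effect inverse-variance pooling
  (β̂ = Σwᵢβᵢ/Σwᵢ, w = 1/se², two-sided p from Z in log space), allele
  harmonization with a declared palindromic-variant policy, filtering on
  contributing studies (≥2) and total cases (≥30,000), transitive 500 kb
  locus clumping, novelty annotation against reported variants (new ⇔
  r² < 0.2 with every reported variant), Storey q-values with the
  smoother π₀ estimator, between-sex heterogeneity Z tests, and
  cross-ancestry Pearson correlations of aligned betas and frequencies.
- **Conditional selection** — GCTA-COJO-style approximate joint models
  from summary statistics and reference LD: b_joint = B⁻¹Db_marg with
  B = √D R √D, D = 2p(1−p), greedy forward selection with a backward
  check at P_joint ≤ 5×10⁻⁸ (or 2.52×10⁻⁵), collinearity guard at
  r² > 0.9.
- **Functionally informed fine-mapping** — Wakefield approximate Bayes
  factors ABF = √(V/(V+W))·exp(z²W/2(V+W)), per-tissue enrichment
  coefficients γ (log prior-odds for annotated variants) maximized
  across regions under a single-causal model, region selection by
  log-BF increment (> mean + 3 sd across regions, plus a genome-wide
  significant variant), PPA(v) ∝ exp(γa(v))·ABF(v), and minimal 95%
  credible sets.
- **Heritability explained** — multifactorial liability-threshold model:
  per-allele log-odds are inverted to liability-scale effects a through
  the population logistic slope implied by the threshold model at
  baseline risk K (default 0.0719); each variant contributes 2p(1−p)a²,
  reported as a percentage of twin heritability (default H² = 0.4).
- **Consensus gene prioritization** — eight binary predictors per
  candidate gene (ClinVar monogenic, drug/MR, PoPS top-2, high-LD eQTL,
  mouse knock-out, high-LD protein-altering variant, rare-variant
  association, nearest gene); the nominee is the highest unweighted
  vote, tiered at ≥2 (prioritized) and ≥3 (strong); agreement,
  pairwise concordance, and positive-control accuracy summaries; a
  risk-factor-consistency classifier over four trait groups.
- **PRS** — dosage-weighted scoring with allele alignment and a declared
  missing-variant policy, per-SD standardization, decile stratification
  (top/bottom and extremes vs middle 80%), and Cox per-SD hazard ratios
  (`survival`-backed).

## Worked example

```r
library(cadgwas)

cfg    <- sim_config(seed = 42, n_variants = 2000, n_blocks = 100,
                     n_causal = 40, causal_beta_sd = 0.08)
panel  <- simulate_ld_panel(cfg)
truth  <- simulate_truth(panel, cfg)
meta   <- filter_variants(meta_analyze(simulate_summary_stats(panel, truth, cfg)))

cl <- clump_loci(meta[meta$P <= 5e-8, ])
jm <- stepwise_select(meta, panel)

lmod <- liability_model(K = 0.0719, h2_twin = 0.4)
pct  <- percent_heritability_explained(jm$selected$beta_joint,
                                       meta$EAF[match(jm$selected$RSID, meta$RSID)],
                                       lmod)

ann     <- simulate_annotations(panel, truth, cfg)
regions <- build_regions(cl$loci, meta, ann)
fit     <- fit_enrichment(regions, "tissue01")
cs      <- credible_set(reweighted_ppa(regions[[1]], fit$gamma, "tissue01"))

model  <- prs_model(data.frame(rsid = truth$causal_rsid,
                               ea = panel$variants$ea[truth$causal_index],
                               weight = truth$beta[truth$causal_index]))
cohort <- simulate_cohort(truth, model, cfg, panel)
sc     <- prs_score(cohort, model)
```

Key numbers from this run (seed 42; formatted from the objects above):

```
significant variants: 274 in 25 loci
<joint_model> 27 selected signal(s) at p <= 5e-08
heritability explained: 4.9%
tissue01 gamma-hat = 2.51 (95% CI 1.56 to 3.51), true ln(5) = 1.61
region 1: 95% credible set of 1 variants; top PPA 1.00
PRS: HR per SD = 1.58 (95% CI 1.50-1.67); top/bottom decile ratio 5.4
```

Reading it: 274 genome-wide significant variants collapse to 25 loci and
27 conditionally independent signals (two loci carry secondary signals);
those signals explain 4.9% of an assumed 40% liability-scale twin
heritability at population risk 7.19%; the enrichment fit recovers the
simulated five-fold annotation enrichment (true ln 5 ≈ 1.61 inside the
CI) and fine-maps the first region to a single variant; the polygenic
score built from the true causal effects yields a hazard ratio of 1.58
per SD and a 5.4-fold event-rate difference between the top and bottom
score deciles.

A command-line wrapper covers the same steps on TSV files
(`exec/cadgwas simulate|meta|clump|fdr|cojo|h2|prioritize|prs`).

## Documentation

The methods vignette (`vignettes/post_gwas_pipeline.Rmd`) describes the
models, the synthetic-data generator's stated world and its limits, and
every numerically consequential design choice.
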