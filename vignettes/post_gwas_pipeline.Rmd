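---
title: "Methods: the post-GWAS analysis chain in cadgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the post-GWAS analysis chain in cadgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters
that matter, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. Meta-analysis

Per-study effects for one variant, aligned to a single effect allele,
are pooled by fixed-effect inverse-variance weighting:
$\hat\beta = \sum_i w_i \beta_i / \sum_i w_i$, $w_i = 1/\mathrm{se}_i^2$,
$\mathrm{se} = (\sum_i w_i)^{-1/2}$. This is exactly the
weighted-least-squares closed form, which the tests verify against an
`lm` oracle. Two-sided p-values come from the pooled Z score through the
normal tail computed in log space; the tail is finite for |z| well
beyond 40, and a p-value is floored at the smallest positive double
rather than ever being returned as exactly zero (the exact tail is
always available as `log10_p`).

**Allele harmonization.** Swapped allele pairs flip the sign of beta
and complement the frequency; strand-complement matches are accepted by
default. Palindromic (A/T, C/G) variants are strand-ambiguous: the
default policy drops them with a warning when MAF > 0.4 and otherwise
aligns them by frequency (orientations chosen so both frequencies fall
on the same side of 0.5). No convention for this is universal; the
policy here is declared, configurable (`palindrome_policy = "keep"`),
and exercised by the generator, which stores a random 20% of rows on
the opposite allele.

**Filtering, clumping, novelty.** Variants present in fewer than two
studies or with fewer than 30,000 total cases are dropped (both
thresholds configurable). Clumping is single-linkage within 500 kb:
chains of significant variants collapse into one locus, the sentinel is
the minimum-p member with position as tie-break. A locus is *new* only
when no previously reported variant lies inside it and the sentinel's
r² with every nearby reported variant is strictly below 0.2 — the
boundary value 0.2 counts as known, and a sentinel absent from the LD
panel yields `"unassessed"` rather than a silent `"new"`.

**FDR.** Storey q-values with the smoother π₀ estimator (natural cubic
smoothing spline over λ ∈ {0.05, …, 0.95}, evaluated at λ = 0.95,
clamped to (0, 1]; below 100 p-values the smoother is unstable and π₀
is conservatively set to 1). Forcing π₀ = 1 reproduces
Benjamini–Hochberg step-up values exactly, which is the oracle the
tests use.

**Sex heterogeneity and cross-ancestry comparison.** Between-sex
heterogeneity uses z = (β_m − β_f)/√(se_m² + se_f²); a variant is
flagged when genome-wide significant in at least one stratum and
heterogeneity p ≤ 0.01. Cross-ancestry comparison reports Pearson
correlations of allele-aligned betas and frequencies over a supplied
sentinel list, with caller-specified outlier exclusion re-estimation.

## 2. Approximate conditional selection

Joint effects for a variant subset solve the LD-weighted normal
equations of the standard summary-statistic approximation: with
reference frequencies p and D = 2p(1−p),
$\hat b_{joint} = B^{-1} D \hat b_{marg}$, $B = \sqrt{D}\,R\,\sqrt{D}$,
which reduces to the marginal estimates under identity LD. The
phenotypic variance entering the joint standard errors is the median
per-variant implied variance $D_j(N\,\mathrm{se}_j^2 + \hat\beta_j^2)$
— the median rather than the mean so outlier standard errors cannot
skew it. Reference-panel frequencies drive D by default
(`freq_source = "meta"` switches).

Selection is greedy forward from the smallest-p variant, admitting at
each step the candidate with the smallest joint p-value if it passes
the threshold, with a backward pass dropping any selected variant whose
joint p rises above the threshold; candidates with r² > 0.9 to the
current selection are excluded (this also guarantees invertibility).
The reference tool's exact collinearity and windowing settings are not
published for the analysis this mirrors, so 0.9 is declared here and
surfaced as an argument. Effective sample size is
N_eff = 4/(1/N_cases + 1/N_controls), the standard case-control
asymptotics.

## 3. Functionally informed fine-mapping

Evidence per variant is the Wakefield approximate Bayes factor,
computed in log space. The prior effect variance W defaults to 0.04
(prior sd 0.2 on the log-odds scale), the conventional choice for
binary traits; it is an argument everywhere it appears.

Each region is assumed to contain at most one causal variant. With a
binary annotation a(v) and enrichment coefficient γ, the causal prior
within a region is π(v) ∝ exp(γ a(v)), and γ is estimated by maximizing
∏_regions (1 + Σ_v π(v)·ABF(v)), the "+1" accounting for the
no-causal configuration. The 95% CI comes from the profile likelihood
(drop of 1.92); the reported sd of γ is the CI width over 2×1.96.
Constant annotations (all 0 or all 1) raise a non-identifiability error
rather than returning a boundary estimate.

**Regions** are built by expanding each clumped locus to ±500 kb around
its sentinel and merging overlaps — the upstream analysis this chain
reproduces used "distance-based regions" without publishing their exact
construction, so this operationalization is declared and configurable.

**Region selection.** A region is *strongly enriched* when its log-BF
increment (log-BF at γ̂ minus log-BF at γ = 0) exceeds the across-region
mean plus 3 sd of increments for that tissue, and it contains a
genome-wide significant variant. Whether the "3 sd" reference should be
the across-region increment distribution or the sd of γ̂ itself is
ambiguous; both are implemented (`baseline = "regions"` is the
default, `"gamma_sd"` the alternative). Note the across-region baseline
flags *outlier* regions: in a world where all regions are equally
enriched, none stands out, and the selected set is legitimately empty.
The selected tissue is the argmax increment, ties broken by tissue
order.

**Credible sets.** PPAs are prior-weighted normalized ABFs (log-space
renormalization, so a region whose ABFs all underflow still sums to 1).
The 95% credible set is the minimal PPA-descending prefix reaching
0.95. Ties in PPA are broken by stable rank — original variant order —
keeping the set minimal and deterministic; with 100 equal PPAs the set
has exactly 95 members. (The alternative of including all boundary-tied
variants would make the uniform case return all 100, which contradicts
minimality; minimality won.)

## 4. Liability-threshold heritability

Disease is modeled as a latent standard-normal liability exceeding
t = Φ⁻¹(1−K); defaults are K = 0.0719 and twin heritability
H² = 0.4. A variant with per-allele liability effect a and frequency p
contributes 2p(1−p)a² of liability variance. The observable per-allele
log-odds β is mapped to a by inverting the *population logistic slope*:
under the threshold model the three genotype classes have exact risks,
and the infinite-sample logistic MLE of disease on genotype is the
unique maximizer of the population logistic likelihood over those
classes. This forward map is solved with BFGS and inverted with a
bracketing root-finder whose upper bound expands geometrically and
stops if the forward map loses monotonicity (which happens only where
all genotype risks underflow). The map is odd under the joint
relabeling (a, p) → (−a, 1−p) — not in a alone — and negative betas are
solved on the relabeled allele, making the variance exactly invariant
to allele relabeling.

Because the logistic slope is invariant to outcome-dependent sampling
(case-control ascertainment moves only the intercept), the same
transformation applies to prospective and case-control estimates; the
`case_fraction` argument is accepted for interface completeness and
documented as a no-op. Among published variants of this transformation
(with and without ascertainment correction), this is the
slope-invariance one; the tests validate it against an individual-level
Monte-Carlo oracle rather than against any published table.

Percent heritability explained is 100 × Σ variance / H², additive over
conditionally independent variants; joint betas are the intended input,
marginal betas are accepted (the caller sees the same number the dual
reporting convention would produce). Results above 100% warn and are
returned as computed.

## 5. Consensus gene prioritization

Eight binary predictors per candidate gene, in fixed column order:
ClinVar monogenic, drug-or-MR, PoPS top-2, high-LD eQTL, mouse
knock-out, high-LD protein-altering, rare-variant association, nearest
gene. The nominee is the gene with the highest unweighted predictor
sum; ≥2 concordant predictors make a locus *prioritized*, ≥3 *strong*.
No published tie rule exists, so ties are reported with a flag and
never silently broken; tied loci are excluded from agreement and
concordance denominators by default (`include_tied = TRUE` counts a
tied locus as agreeing when the predictor marks any tied nominee), and
positive-control evaluation counts a tied locus as correct, flagged,
when the truth gene is among the tied set. Whether accuracy
denominators should be all control loci or only predictor-informative
loci is also ambiguous; both are reported
(`accuracy_all`, `accuracy_fired`).

## 6. Polygenic scores

Raw score = Σ dosage × weight after effect-allele alignment; model
variants absent from the cohort are mean-imputed at 2×EAF by default
(matching common scoring-tool behavior) or dropped via
`missing = "drop"`. Standardization is within the scored cohort, as are
decile boundaries ("percentile relative to the total cohort"). Decile
assignment uses stable ranks, so it is invariant to monotone transforms
of the score; a reference stratum with zero events yields an infinite
ratio with a flag rather than an error. The survival association is a
thin wrapper over `survival::coxph` with declared covariates (age, sex,
PC1–5 by default); non-convergence is flagged, never silently
defaulted.

## 7. The synthetic world

The generator's defaults describe one fixed, documented world; they are
statements about the data, not tuning knobs:

- 5,000 variants in 50 AR(1) LD blocks with ρ = 0.9, blocks placed
  ≥2 Mb apart so physical distance and LD agree; frequencies uniform on
  [0.01, 0.5]; alleles randomized so alignment code is exercised.
- 50 causal variants with per-allele log-odds effects N(0, 0.05²) —
  the weak-effect regime (odds ratios mostly 1.02–1.10) that dominates
  a modern coronary-disease meta-analysis.
- Four case-control studies of 20,000 cases / 80,000 controls each.
  Marginal effects are the LD projection of joint effects in
  standardized genotype units (u_marg = R u_joint); noise has
  covariance σ²R/N_eff per study with σ² = 4, which reproduces
  var(β̂) = (1/N_cases + 1/N_controls)/(2p(1−p)).
- Baseline population risk K = 0.0719; twin heritability 0.4.
- Ten annotation tissues at 10% background coverage, the first with a
  five-fold causal/non-causal annotation odds ratio, the rest null.
- Two ancestries with causal-effect correlation 0.6.
- Eight predictors with sensitivity 0.8 and specificity 0.95: no
  published per-predictor error rates exist, so these are documented as
  synthetic defaults, deliberately mid-range so both successes and
  failures occur. All eight fire independently per the stated contract;
  the nearest-gene predictor is instead deterministic from simulated
  gene coordinates (≥3 genes per locus, uniform within ±500 kb of the
  sentinel). When ingesting a real PoPS gene list the two top genes per
  locus are both marked, but the generator does not impose that shape.
- A cohort of 20,000 with events from a logistic model calibrated to
  marginal rate K, default per-SD effect log(1.6), follow-up 5 years
  with uniform event times — between a short secondary-prevention trial
  and a long population cohort, adequate for rank-based stratification
  and Cox fitting, which is all the module claims.

All randomness flows from one master seed; every generator derives its
own sub-stream, so invocation order cannot change results, and
identical configurations are byte-identical.

**What the generator does not emulate** — and therefore what a green
test does not establish: realistic human LD (no haplotypes, no MAF-LD
coupling, no long-range structure), between-study heterogeneity,
imputation error beyond a cosmetic INFO column, LD between PRS variants
in the cohort (dosages are drawn independently), competing risks or
informative censoring, and any correlation structure among the eight
predictors. Conclusions about calibration and recovery hold for the
stated world; transfer to real data rests on the analytical
derivations, not on these simulations.

## 8. Numerical choices

- p-values: log-space normal tails; floor at the smallest positive
  double; `log10_p` carried alongside.
- PSD tolerance for LD matrices: 1e−8, checked by eigendecomposition in
  tests.
- PPA normalization: log-sum-exp; sums verified to 1 within 1e−8.
- Enrichment optimization: golden-section on γ ∈ [−10, 10]; profile-CI
  roots to 1e−5.
- Liability inversion: uniroot to 1e−9 on a monotonicity-guarded
  bracket.
- The novelty r² boundary applies a 1e−12 tolerance so that a
  correlation stored as √0.2 squares back to "exactly" 0.2.

## 9. Known limitations

- One causal variant per fine-mapped region; multi-signal regions are
  not decomposed into per-signal credible sets.
- One annotation per tissue (the merged functional state); no
  multi-annotation penalized model.
- The conditional-selection module targets desk-scale chromosomes (no
  sliding LD windows, no MAF-difference filters).
- PRS weight derivation (LDpred, pruning and thresholding) is out of
  scope; only scoring and evaluation are implemented.
- The heritability transformation assumes Hardy–Weinberg genotype
  frequencies and a single-variant logistic fit; rare frequencies with
  extreme effects can leave the invertible domain, which raises an
  explicit error.
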