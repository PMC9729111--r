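Package: cadgwas
Title: Post-GWAS Analysis Chain for Case-Control Meta-Analyses
Version: 0.1.0
Authors@R:
    person("CAD", "Genomics Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of the analytical chain that
    follows a large case-control genome-wide association meta-analysis:
    fixed-effect inverse-variance meta-analysis with variant filtering,
    locus clumping and novelty annotation, Storey q-value FDR thresholds,
    sex-heterogeneity tests, cross-ancestry comparison, approximate
    stepwise conditional/joint selection from summary statistics and an LD
    reference, functionally informed fine-mapping with annotation-enriched
    priors and 95 percent credible sets, liability-threshold heritability
    explained, an eight-predictor consensus causal-gene prioritization
    framework with its evaluation statistics, and polygenic-score
    stratification. A synthetic-data module generates every input the
    pipeline consumes so the full chain is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
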