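Package: microgwas
Title: Host Genetics and Gut Microbiome Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Signature-gene metagenomic species profiling with negative
    binomial outlier filtering, KEGG module completeness profiling,
    covariate-adjusted microbiome genome-wide association with inverse
    rank-normal transformed traits, METAL-style fixed-effect and
    sample-size-weighted meta-analysis, GREML SNP heritability, two-sample
    Mendelian randomization (Wald ratio, IVW, MR-Egger, weighted median)
    and approximate-Bayes-factor colocalization, together with a synthetic
    cohort generator with planted genetic and causal effects so the whole
    pipeline can be exercised end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
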