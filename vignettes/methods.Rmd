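---
title: "Methods: from signature-gene counts to host-genetic causes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from signature-gene counts to host-genetic causes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgwas)
```

`microgwas` implements the computational core of a host-genetics study of
gut microbiome composition: quantifying species from metagenomic
signature-gene read counts, building KEGG-module functional profiles,
testing genetic variants against transformed abundance traits, estimating
SNP heritability, and probing causal structure with two-sample Mendelian
randomization and colocalization. Every stage can be exercised against a
synthetic cohort generator with planted, known effects. This vignette
records the models, the parameter choices that matter, and the design
decisions taken where more than one reasonable convention exists.

## Species quantification from signature genes

Each species is represented by up to 250 *signature genes*: core genes
(at least 60% prevalence across the species' genome assemblies) of
200 bp to 20 kb that are unique to the species. When more genes are
eligible than the cap allows, selection is deterministic — higher MAG
prevalence first, then longer genes, then lexicographic id — so repeated
runs select identical panels (`select_signature_genes()`).

Read pairs are classified against the catalog before counting
(`classify_read_pairs()`): a read maps uniquely when MAPQ ≥ 20, identity
≥ 95% over ≥ 100 aligned bp, and at most 10 bases fail to align; a pair
is counted for a gene if either read maps uniquely, and when both reads
are unique to different genes only read one's gene is counted.

Within a species and sample, the count of signature gene $g$ is modelled
as negative binomial with mean proportional to its effective length
$L_g$ (gene length minus the 100 bp minimum alignment length, plus one)
and size parameter $r_g = \log_2 L_g$, variance $\mu + \mu^2/r$. Three
conventions deserve note, since "dispersion" alone does not pin down a
parameterization:

* the size (not the variance-inflation) reading of the dispersion is
  used, clamped below at 1 for very short genes;
* the central 99% interval is the 0.5%–99.5% quantile pair of that
  distribution, *inclusive* at both ends;
* the expected-nonzero criterion is the mean over the species' genes of
  $P(X_g > 0)$ under the fitted model.

`estimate_abundances()` then applies, in order: (1) if ≥ 50 signature
genes are non-zero and ≥ 99% of genes are expected non-zero, zero-count
genes are ignored; (2) genes with counts outside their 99% interval are
excluded; (3) abundance is the mean of count/$L_g$ over admitted genes;
(4) species with fewer than five non-zero in-bounds genes are zeroed;
(5) species with under 66% of considered genes non-zero-in-bounds are
zeroed unless the median length-corrected abundance over their signature
genes is positive, in which case that median (over non-zero genes) is
used; (6) rows are normalized to 100%. The denominator of the 66% rule
is the gene set *after* zero-ignoring — a convention this package fixes
explicitly, and the choice is recorded per cell in the `flag` attribute
so downstream users can audit which rule fired.

Rarefaction (`rarefy_profile()`, default target 164,245 signature-gene
counts) subsamples each sample's count multiset without replacement;
samples below the target are excluded rather than erroring, matching
cohort-QC practice. Alpha diversity uses the natural-log Shannon index,
the default of the standard community-ecology implementation it is
cross-checked against in the test suite.

## Functional profiles

KO profiles are proportions of total length-normalized gene abundance
(`ko_profile()`). A species is associated with a KEGG module
(`species_module_association()`) when at least one alternative path has
≥ 2/3 of its distinct KOs present — counting KOs, not steps, in
multi-KO steps, a convention the completeness record makes auditable —
and, for paths of three or fewer steps, every step is covered. Module
abundance is the summed relative abundance of associated species, which
makes module profiles bounded by 100 and exactly additive in species.

## Association testing

Abundance traits are inverse rank-normal transformed with the Blom
offset, $\Phi^{-1}((\mathrm{rank} - 3/8)/(n + 1/4))$; 3/8 is the common
default among the several offset conventions in use.
Per-variant tests are ordinary least squares of the transformed trait on
allele dosage plus covariates. The mixed-model/whole-genome-ridge
machinery real cohorts need for relatedness is deliberately not
reproduced: synthetic cohorts are unrelated by construction and the OLS
estimand is identical. Two-sided p-values use the normal approximation
at $n \ge 1000$ and the t distribution below that. Variants with MAF
< 1% are excluded. Conditional scans add each locus index variant
(locus = index ± 500 kb) as a covariate and stop when nothing passes
the entry threshold.

The effective number of tests uses the Li–Ji eigenvalue rule
$M_\mathrm{eff} = \sum_\lambda [\mathbb{1}(\lambda \ge 1) + (\lambda -
\lfloor\lambda\rfloor)]$; because cohort studies often report an
effective-test count estimated with an external tool, `study_threshold()`
also accepts $M_\mathrm{eff}$ directly, so thresholds such as
$5\times10^{-8}/391 = 1.3\times10^{-10}$ (species traits) or
$/102 = 4.9\times10^{-10}$ (module traits) are reproducible without
re-deriving the count.

Meta-analysis follows the METAL conventions: fixed-effect IVW
($\hat\beta = \sum w_i \beta_i / \sum w_i$, $w_i = 1/se_i^2$) when all
studies share a trait scale, and the sample-size-weighted z-score method
($z = \sum z_i \sqrt{n_i} / \sqrt{\sum n_i}$) when they do not — the
situation of a replication cohort analyzed on a centered-log-ratio
rather than rank-normal scale, for which `meta_analyze()` refuses IVW.
Replication requires direction concordance plus $p < 0.05/k$.

## Heritability

`compute_grm()` uses the standard allele-frequency-scaled estimator.
`reml_h2()` fits the one-GRM variance-component model by
average-information REML in the eigenbasis of the GRM (which makes each
iteration O($np^2$) after one decomposition): AI updates with components
clamped at $10^{-6} V_p$, an EM fallback step whenever the AI step fails
or does not improve the restricted likelihood, convergence at
$10^{-6}$ on the log-likelihood, at most 100 iterations, standard
errors from the inverse AI matrix, and a delta-method SE for
$h^2 = V_g/V_p$. Non-convergence flags the result instead of raising.
Haseman–Elston regression (`he_regression()`) — the slope of pairwise
trait cross-products on GRM entries — serves as an independent moment
estimator; the two agree within joint standard errors on simulated
traits, which is the package's main guard against REML implementation
error.

## Mendelian randomization and colocalization

Instruments require exposure $p < 5\times10^{-8}$, MAF > 1%, and greedy
pruning at $r^2 < 0.01$ in a genotype panel, retaining the smaller
p-value of any correlated pair. Estimators: Wald ratio (first-order
delta SE) for single instruments; IVW as weighted regression through the
origin with random-effects SE inflation $\max(1, \sqrt{Q/(k-1)})$ when
Cochran's Q is heterogeneous at $p < 0.05$ (the 0.05 trigger and
multiplicative inflation are this package's documented convention for
Q-dependent model choice); MR-Egger with instruments
oriented to positive exposure effects; and the weighted median with a
1000-resample parametric bootstrap SE under a fixed seed.

The screen of one exposure against hundreds of traits
(`mr_screen()`, `mr_screen_summary()`) reports the nominal-significance
count against the $\alpha \times n$ expectation with a 1-df
observed/expected chi-square *and* an exact binomial p-value: the two
differ in their tails, and reporting both leaves the choice of test
visible rather than baked in. The expected count itself (27.3 for 546
traits at $\alpha = 0.05$) is exact.

Colocalization uses Wakefield approximate Bayes factors with prior
effect SD 0.15 (quantitative) or 0.2 (binary) and hypothesis priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the field's standard
defaults, exposed as arguments. One numerical
subtlety is worth knowing: at fixed z-score the single-variant ABF is
increasing in the standard error until $z^2 > 1 + W/V$, so "weaker data
at the same z" only shifts posterior mass toward the null hypotheses for
genuinely strong signals; the test suite exercises the monotonicity
claim in that regime.

## The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) exists to give every
stage inputs with known ground truth; its defaults are chosen once, on
realism grounds, and the acceptance checks run at fixed configurations
stated below.

* **Compositions.** Latent log abundances are Gaussian: species means
  spread with SD 1.5 (heavy-tailed communities where the top species
  typically holds 10–40% of the community) and within-sample SD 1.
  Compositions are the softmax of the latents.
* **Effects.** Planted SNP and BMI effects act additively on the latent
  log scale *before* closure, in units of the within-sample latent SD,
  so they approximately equal the betas recovered on the IRNT scale.
  The approximation is not assumed away: closure couples species through
  the normalizing denominator, attenuating recovered effects by roughly
  the variance share of the community's dominant species (a few percent
  in 100-species communities, up to ~10–15% when one species holds 40%).
  Recovery checks therefore plant effects on low-share (≈ 0.5–1%)
  species, where a genuine GWAS target like a 1%-abundance organism
  sits, and the attenuation is well inside estimation error.
* **Counts.** Gene counts are drawn from exactly the profiler's NB model
  (mean ∝ composition × effective length × depth, size
  $\log_2 L$), with a configurable fraction of gene-sample cells
  inflated multiplicatively to emulate cross-mapping outliers.
* **Genotypes.** Biallelic HWE dosages; LD blocks share one allele
  frequency and copy haplotype alleles with mutation rate 0.1, giving
  geometrically decaying $r^2$ — sufficient structure for pruning and
  colocalization without a reference panel.
* **Covariates and traits.** Age ~ U(20, 80), sex ~ Bernoulli(0.5),
  eight library plates with small random effects; all three weakly
  affect the BMI-like trait so covariate adjustment is non-trivial. BMI
  instruments (a config extension the screen requires) carry per-allele
  effects of varied magnitude 0.10–0.22 — mirroring the spread of
  reported per-allele effects on abundance traits, and necessary for
  MR-Egger, whose slope is unidentified when all instruments share one
  effect size. A binary disease is drawn from a logistic model on one
  species' standardized abundance.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: compositional zero-inflation beyond
the NB sampling process, relatedness and population structure,
imputation uncertainty, LD from real recombination maps, diet/medication
confounding, and batch structure richer than a plate effect.

## Problem sizes of the shipped checks

The acceptance checks and `scripts/acceptance.R` use: profiler recovery
at 200 samples × 50 species with the 250-gene cap binding and 2 × 10⁶
expected signature read pairs (deep-shotgun order; at this depth the
per-cell estimator SD is ≈ 2%, so a 10% maximum relative error over
~5,000 cells is a ≈ 4 SD bound); GWAS recovery at n = 20,000 and MAF
0.3 for a planted 0.10 SD/allele effect; GREML at n = 1,500 × 2,000
SNPs for planted $h^2 = 0.30$; MR at 12,000 + 12,000 samples with 30
instruments for a planted causal effect of 0.15; the null screen over
546 traits with 200 replicates at n = 1,200; colocalization on
60-variant panels at n = 3,000. These sizes keep full runs in minutes
on one core while leaving each check's Monte-Carlo error well below its
tolerance.

## Known limitations

REGENIE-style whole-genome ridge, LD-score regression, multi-component
GREML, MR-PRESSO/multivariable MR, and LD-aware (SuSiE-style)
colocalization are out of scope. The masking fallback for species with
fewer than 20 unique signature genes is flagged
(`fallback_needed`) but not implemented, as it requires sequence-level
alignment. The classifier operates on abstract alignment records, not
BAM files — alignment itself is upstream of this package.
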