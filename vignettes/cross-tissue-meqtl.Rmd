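---
title: "Cross-tissue meQTL analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue meQTL analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtlcross)
```

## What the package computes

`meqtlcross` implements a complete cross-tissue genetic–epigenetic analysis:

1. **cis-meQTL mapping.** For every SNP–CpG pair on the same chromosome
   within a 20 kb window, methylation is regressed on the additive dosage of
   the SNP's coding allele plus covariates (age, sex, diagnosis, cell-type
   proportion, ancestry PCs). A pair is called a meQTL at p ≤ 1e-5. The
   effect carried forward for cross-study comparison is the *normalized
   coefficient* β̂ = β / std(β) — the t statistic — because raw β values are
   not comparable across studies that normalized methylation differently
   (e.g. rank-normalized blood data), while the sign and genome-wide pattern
   of β̂ are.
2. **Cross-tissue harmonization.** SNPs and CpGs are matched between
   studies by chromosome position; coding alleles are reconciled by direct
   match, strand complement, or allele swap (multiplier −1). Concordance is
   summarized by the same-sign fraction and the Spearman correlation of
   harmonized β̂.
3. **Enrichment.** The SNP universe is LD-pruned (greedy, r² > 0.7)
   with annotation SNPs processed first so they are never sacrificed to a
   non-annotated partner. Significance of an overlap is assessed two ways:
   an empirical `P_perm` from null SNP sets matched to the query's MAF
   histogram (bins of 0.05), and a two-sided Fisher exact test with the
   sample odds ratio ad/bc and a Wald 95% CI.
4. **Consensus co-methylation networks.** Per tissue, an unsigned adjacency
   `|cor|^6` and the topological overlap matrix (TOM); the consensus TOM is
   the element-wise minimum across tissues; modules come from
   average-linkage clustering of 1 − TOM with a static height cut; module
   eigengenes (first PC) are tested for diagnosis association per tissue
   and combined across tissues.

## The synthetic cohort generator

Real multi-tissue cohorts with genotypes and methylation are
restricted-access, so the package ships a generator
(`cohort_spec()` / `build_cohort()`) that plants known ground truth:

* **Genotypes** are biallelic dosages drawn Binomial(2, p) per SNP —
  exactly Hardy–Weinberg — with p uniform in `maf_range` on a single
  chromosome with strictly increasing 1-based positions.
* **Methylation** is generated on the logit scale and mapped through the
  inverse logit, which guarantees beta values in (0, 1):
  `logit(m) = baseline + Σ effect·dosage + covariate terms + batch shift +
  module factor + N(0, noise_sd)`.
* **Planted cis effects**: a fraction `frac_cis_pairs` of CpGs receives a
  cis SNP (within 20 kb); a fraction `frac_shared` of those effects is
  present in all tissues *with identical size and sign* (this makes
  sign-concordance checks crisp; the real studies report same-sign,
  similar-rank effects), the rest in exactly one tissue.
* **Disease modules** act through a shared latent factor per module: the
  factor has mean `module_effect · diagnosis` and unit variance, and module
  CpGs load on it with loadings U(0.8, 1). A flat per-CpG case–control
  shift would shift means without creating co-methylation; the latent
  factor produces both the correlation structure a TOM can detect and the
  eigengene-level disease association, which is the phenomenon of interest.
* **Annotation sets** (`plant_annotation_set()`) are planted at a target
  odds ratio against the true meQTL SNPs by drawing the overlap count from
  Fisher's noncentral hypergeometric distribution with odds equal to the
  target, then sampling members uniformly within strata.
* **LD** is off by default (each SNP independent); `simulate_ld_partner()`
  copies a column with partial resampling to reach a target r², which is
  how the pruning tests build correlated pairs and chains.

Default cohort sizes mirror the three studies this pipeline emulates
(prefrontal cortex n = 258, whole blood n = 837, saliva n = 197 with
roughly half cases), with 500 SNPs and 500 CpGs on a 5 Mb chromosome as a
demonstration scale. Tests and the acceptance script use smaller or
purpose-built specs (noted in each test) so the whole suite runs in
minutes; the statistical behaviour being checked (calibration, recovery,
concordance) is scale-free or checked against analytic expectations.

The generator does **not** emulate realistic LD structure, probe-level
array artifacts, cell-type mixture signals, trans effects, or genome
annotation; passing tests demonstrate that the statistical machinery is
correct under the stated generative model, not that it is robust to every
artifact of real array data.

Effect-size and noise defaults are not taken from the emulated studies
(which do not publish a generative model): logit-scale effects U(0.3, 0.8)
with residual SD 0.3 give per-pair detection power spanning roughly
0.3–1.0 at n ≈ 200 and p ≤ 1e-5 — a regime where detection is neither
saturated nor hopeless, matching the qualitative power analysis the
source studies describe. They were fixed once and are spec parameters,
not tuning knobs.

## Preprocessing

The order is: blacklist filter → detection-p masking (p > 0.05 treated as
missing) → missingness filter (> 1%) → quantile normalization → per-CpG
mean imputation → batch adjustment. The emulated studies list these steps
without a strict order for normalization vs imputation; normalizing first
avoids imputed values distorting the quantiles. Quantile normalization
forces every subject to the across-subject mean of order statistics
(average ranks on ties). Batch adjustment uses the parametric
empirical-Bayes scheme of ComBat with diagnosis protected in the design by
default (the studies do not state whether their ComBat design carried
covariates; protecting diagnosis is the conservative choice and is a
documented flag). On noise-free input the EB standardization is degenerate
(zero residual variance); the implementation detects this and falls back to
removing batch means by linear regression conditional on the protected
covariates, which preserves the exact-identity behaviour the degenerate
case calls for.

Hardy–Weinberg testing is a 1-df chi-square goodness-of-fit against the
sample allele frequency, with Yates continuity correction when the
smallest expected count is below 5 (the threshold in the emulated QC is
tool-agnostic; an exact test would also serve but adds nothing at the
sample sizes involved). Rank normalization uses Blom offsets
`qnorm((rank − 3/8)/(n + 1/4))` with average ranks on ties.

## Scan numerics

The fast path residualizes the dosage and methylation matrices on the
covariate design once and forms correlation-based t statistics per cis
pair; by Frisch–Waugh–Lovell this equals the per-pair OLS fit (the
acceptance suite verifies equality to < 1e-8; observed agreement is at
machine precision). Degrees of freedom are n − (covariates + 2). Pairs
with a constant dosage after pairwise-complete removal are flagged and
excluded rather than fit. The cis window is boundary-inclusive
(|pos_SNP − pos_CpG| ≤ 20,000), a choice the source description ("within
20 kbp") leaves open; inclusivity is asserted in tests so the convention
cannot drift.

Analytic power for the slope t-test uses noncentrality
`effect · sqrt(n · 2 · maf · (1 − maf))` on n − 2 df, with `effect` in
residual-SD units. The emulated power analysis does not print its alpha or
model; this formula is a documented reconstruction validated against
Monte-Carlo rejection rates (agreement within 2% is an acceptance
criterion).

## Harmonization choices

Palindromic SNPs (A/T, C/G) are dropped during allele harmonization with a
recorded reason: without allele frequencies the strand cannot be resolved,
and the emulated analyses are silent on the point. Matching is by
chromosome position, not rsid. Sharing itself is defined by position
matching alone; the allele harmonization (and its palindromic drops) gates
only the effect-sign and rank comparisons, so shared-pair counts are
consistent between pairwise and all-tissue intersections. The denominator
for each tissue's "fraction shared" is that tissue's own significant set
restricted to the common SNP/CpG universe. In restricted mode, matched pairs are first filtered to
MAF-concordant pairs (difference < 0.1 by default) whose implied
per-allele effects reach 0.8 analytic power at a reference n of 200,
mirroring the power-controlled sensitivity analysis of the emulated
comparison. A β̂ of exactly zero is counted as positive sign and tallied
separately (`n_zero`).

## Enrichment numerics

The permutation statistic — the overlap proportion of a MAF-bin-matched
random SNP set — depends only on the per-bin overlap counts, so the
default implementation draws those counts directly from the hypergeometric
distribution per bin. This is *exactly* the null distribution of sampling
explicit sets without replacement (the package can also materialize sets,
and a test confirms the two paths agree in distribution), and it is what
makes 1e5-set permutation runs and 500-replicate calibration studies cheap
on one CPU. The empirical p uses a strict ">" and p = 0 is reported as
"< 1/n_sets". MAF bins are [0, 0.05), …, [0.45, 0.5] with the last bin
right-closed. The Fisher CI is Wald on the log odds ratio with Haldane's
0.5 correction for zero cells (the emulated reports do not state their CI
construction; Wald is labelled in the output). The exact p-value sums
hypergeometric probabilities of tables no more probable than the observed
one.

Greedy LD pruning processes annotation-priority SNPs first (by position),
then the rest (by position), keeping a SNP iff its r² with every kept SNP
within the window is ≤ the threshold; tests verify the kept set is
conflict-free, maximal, and priority-optimal against exhaustive search.

## Network numerics

TOM follows `(Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij)` with unit
diagonal. Module detection replaces dynamic tree cut with a static cut at
0.995 of the maximum merge height plus a minimum size of 30: the emulated
analysis names WGCNA but specifies no cut parameters, and a static cut is
self-contained and directly testable (planted-module recovery at
Jaccard ≥ 0.8 and suppression of single-tissue modules in the consensus
are acceptance criteria). Module eigengenes are unit-variance first-PC
scores oriented so their mean correlation with module CpGs is positive.

Two cross-tissue combinations are provided. `combined_p` defaults to
Fisher's method (−2Σ log p on 2k df) as the emulated description states.
The worked two-tissue case in that description, however — per-tissue p of
5.33e-3 and 2.87e-4 printed as a combined 5.5e-6 — is *not* what Fisher's
formula yields (≈ 2.2e-5); a Stouffer combination of the printed T
statistics gives ≈ 5e-6. The intended method is ambiguous, so both are
computed (`combined_p_fisher`, `combined_p_stouffer`) and the default is
documented rather than reconciled. Module membership combines Fisher
r-to-z transformed CpG–eigengene correlations across tissues by Stouffer
(whether the emulated MM used correlation p-values or r-to-z is unstated;
r-to-z is the standard choice and is documented). Methylation significance
combines signed z-equivalents of the per-CpG diagnosis t statistics.
Tissues whose model is degenerate (e.g. no diagnosis contrast) are dropped
from combinations rather than poisoning them.

## Degenerate inputs and tie-breaks

* Constant CpGs: rank normalization and adjacency construction error with
  the offending columns listed; constant dosages yield flagged,
  excluded records; constant vectors in r² yield 0 with a warning.
* Ties in quantile/rank normalization use average ranks.
* Single batch: batch adjustment warns and returns its input.
* Empty intersections (no cis pairs, no shared pairs, empty meQTL tables)
  warn and propagate empty results; the pipeline completes.
* Fisher tables with an empty margin error (SNP-set test) or are skipped
  with a note (context scan over many contexts).

## Limitations

The static tree cut will not separate nested or overlapping modules the
way dynamic tree cut can, and no module merging by eigengene correlation
is performed. Only cis effects are modelled and scanned. The permutation
test conditions on the realized MAF histogram of the query; queries that
concentrate in sparse MAF bins will exhaust a small universe (this errors
with the offending bin named rather than silently resampling). ComBat
assumes roughly Gaussian per-CpG intensities; on raw beta values near 0
or 1 its location/scale model is approximate, which matches how the
emulated preprocessing used it.
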