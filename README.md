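# meqtlcross

Cross-tissue analysis of genetic effects on DNA methylation: cis-meQTL
mapping in several tissues, cross-tissue harmonization and concordance
statistics, MAF-matched permutation enrichment of meQTLs in annotation sets
(disease risk loci, eQTLs, CpG genomic contexts), and consensus
co-methylation network analysis with disease-association statistics.

## The problem

Brain tissue is rarely available in psychiatric epigenetics, so peripheral
tissues (blood, saliva) are used as surrogates. Whether that is defensible
depends on how much of the genetic control of methylation is shared across
tissues. A methylation quantitative trait locus (meQTL) is a SNP whose
dosage predicts the methylation level of a nearby CpG; if the same
SNP–CpG pairs show the same direction and relative strength of effect in
brain and periphery, and those shared meQTLs are enriched in disease risk
loci, peripheral meQTLs carry information about brain regulation.
`meqtlcross` packages the full analysis for that question, together with a
synthetic multi-tissue cohort generator with planted ground truth so every
stage is testable without restricted cohort data.

## The statistics

* **cis-meQTL scan.** For each same-chromosome SNP–CpG pair with
  |pos_SNP − pos_CpG| ≤ 20 kb, fit m = α + β·g + γᵀC + ε by OLS (g =
  coding-allele dosage, C = age, sex, diagnosis, cell proportion, ancestry
  PCs). Keep pairs with p ≤ 1e-5. The cross-study effect measure is the
  normalized coefficient **β̂ = β / std(β)**; its sign gives the direction
  of regulation and its genome-wide pattern the relative effect strength.
* **Concordance.** After matching SNPs/CpGs by position and harmonizing
  coding alleles (strand flip and allele swap where needed; palindromic
  SNPs dropped), report the same-sign fraction of β̂ and the Spearman ρ of
  effect patterns between tissues.
* **Enrichment.** On an LD-pruned universe (greedy r² > 0.7, annotation
  SNPs kept with priority), compare the observed annotation overlap of a
  query SNP set against null sets matched to the query's MAF histogram
  (bins of 0.05): empirical **P_perm**, plus a Fisher 2×2 exact test with
  sample odds ratio and Wald 95% CI (**P_Fisher**).
* **Consensus networks.** Per tissue, adjacency a_ij = |cor(m_i, m_j)|⁶
  and the topological overlap matrix TOM_ij = (Σ_u a_iu a_uj + a_ij) /
  (min(k_i, k_j) + 1 − a_ij); consensus = element-wise minimum across
  tissues; modules by average-linkage clustering of 1 − TOM (static cut);
  module eigengene (first PC) tested against diagnosis per tissue and
  combined across tissues (Fisher's method; Stouffer provided), with
  per-CpG module membership (MM) and methylation significance (MS)
  combined as cross-tissue Z-scores.

## Worked example

```r
library(meqtlcross)

spec <- cohort_spec(
  n_subjects = c(brain = 150, blood = 150, saliva = 150),
  n_snps = 300, n_cpgs = 300, chrom_length = 3e6,
  frac_cis_pairs = 0.2, frac_shared = 0.7, seed = 11
)
cohort <- build_cohort(spec)

tables <- purrr::imap(cohort$tissues, function(td, tissue) {
  scan_tissue(td$geno, td$meth, td$covariates, tissue = tissue)
})
glance(tables$brain)
#> # A tibble: 1 × 7
#>   tissue window p_threshold n_pairs_tested n_significant n_meqtl n_cpg
#>   <chr>   <dbl>       <dbl>          <int>         <int>   <int> <int>
#> 1 brain   20000     0.00001           1266            42      37    42

ov <- overlap_summary(tables)
dplyr::select(ov$pairwise, tissue_a, tissue_b, n_shared_pairs,
              frac_pairs_a, same_sign_fraction, spearman_rho)
#> # A tibble: 3 × 6
#>   tissue_a tissue_b n_shared_pairs frac_pairs_a same_sign_fraction spearman_rho
#>   <chr>    <chr>             <int>        <dbl>              <dbl>        <dbl>
#> 1 brain    blood                31        0.738                  1        0.956
#> 2 brain    saliva               29        0.690                  1        0.955
#> 3 blood    saliva               30        0.75                   1        0.931
ov$threeway
#> # A tibble: 1 × 3
#>   n_shared_pairs n_shared_meqtl n_shared_cpg
#>            <int>          <int>        <int>
#> 1             29             26           29

uni <- cohort$tissues$brain$geno$snp_meta[, c("snp_id", "maf")]
enr <- snp_enrichment(query = unique(tables$brain$snp_id),
                      annotation = cohort$truth$risk_snps,
                      universe = uni, n_sets = 10000, seed = 11)
enr
#> # A tibble: 1 × 11
#>   observed_proportion p_perm n_sets odds_ratio ci_lo ci_hi p_fisher     a     b
#>                 <dbl>  <dbl>  <dbl>      <dbl> <dbl> <dbl>    <dbl> <int> <int>
#> 1               0.351 0.0024  10000       3.31  1.55  7.07  0.00347    13    24
```

Reading the output: 42 of 1266 tested cis pairs are significant in "brain";
about 69–75% of each tissue's significant pairs are shared pairwise (the
cohort was simulated with 70% shared effects), shared effects are 100%
sign-concordant with Spearman ρ ≈ 0.93–0.96, and the detected meQTLs
overlap the planted risk-SNP annotation far more than MAF-matched null
sets (P_perm = 0.0024, OR = 3.31).

`run_pipeline(pipeline_config(spec = spec), "out/")` runs
simulate → QC → scan → compare → enrich → network end to end, writing every
stage table as TSV plus a report that echoes all thresholds.
`autoplot()` methods cover matched-pair effect scatters, enrichment forest
plots, and module MM/MS panels; `tidy()`/`glance()` return tibbles for all
result types.

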