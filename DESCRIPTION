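Package: meqtlcross
Title: Cross-Tissue meQTL Mapping, Enrichment, and Consensus Co-Methylation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping cis-acting methylation quantitative trait loci
    (meQTLs) in several tissues, harmonizing alleles and comparing effect
    patterns across tissues, testing enrichment of meQTLs in annotation sets
    (disease risk loci, eQTLs, CpG genomic contexts) with MAF-matched
    permutation nulls and Fisher exact tests, and building consensus
    topological-overlap co-methylation networks with module-level disease
    association statistics. Includes a synthetic multi-tissue cohort generator
    with planted cis effects, batch structure, and disease modules so the whole
    pipeline can be exercised and validated without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
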