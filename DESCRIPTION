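Package: condgwas
Title: Conditional GWAS of Correlated Methylation Traits in Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear mixed-model association mapping for pairs of strongly
    correlated quantitative traits, built around the conditional-GWAS idea of
    scanning one trait while controlling for the other as a fixed covariate.
    Provides bisulfite methylation phenotyping from per-cytosine calls
    (weighted methylation over transposon annotations, RdDM/CMT2 target
    classification), identity-by-state kinship, REML variance components and
    SNP-heritability, EMMAX-style univariate/conditional scans, a bivariate
    multi-trait mixed model (common/specific/any effect decomposition),
    a priori candidate-gene enrichment with a genome-rotation null and an FDR
    upper bound, and allele-frequency-matched permutation tests for geographic
    clines, inter-locus LD, and epistatic effects on transposon insertion
    counts. Ships a synthetic-data generator emulating structured inbred
    panels so the whole pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
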