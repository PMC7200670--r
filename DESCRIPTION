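Package: iqtlkit
Title: Immune Infiltration Scoring and Infiltration-QTL Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating infiltrating immune cell content from bulk
    expression profiles with three complementary scoring methods (constrained
    regression relative fractions, scaling-factor absolute scores, and
    rank-based enrichment scores), defining and filtering tissue-by-cell-type
    infiltration phenotypes, scanning for demographic and genetic associations
    with Empirical Brown's method for combining dependent P-values,
    detecting immune-hot and immune-cold samples by consensus k-means and
    quintile membership, and testing iQTL sets for eQTL and GWAS-catalog
    enrichment against MAF- and LD-matched permutation nulls. Includes a
    synthetic cohort generator with planted age, sex and per-SNP effects so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pracma,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
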