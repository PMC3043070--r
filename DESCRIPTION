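Package: mirpivot
Title: Integrated miRNA-mRNA Differential Expression and Ranked-List
    Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact combinatorial two-class differential expression via the
    TNoM (threshold number of misclassifications) statistic, exact
    minimum-hypergeometric (mHG) gene-set enrichment over ranked lists, and
    a pivot-miRNA correlation framework linking miRNA expression to
    biological processes in paired miRNA-mRNA expression cohorts.  Provides
    microarray-style preprocessing (replicate averaging, percentile
    normalization, detection filtering), proliferation phenotype and
    lysate-microarray screen-hit rules, and a synthetic paired-cohort
    generator with planted differential features, co-expression modules and
    target regulation for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
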