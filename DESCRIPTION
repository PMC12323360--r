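Package: gutindices
Title: Gut Microbiome Health Indices from Taxonomic Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-sample gut dysbiosis indices from taxonomic
    abundance tables: the metagenomic aerotolerant predominance index
    (MAPI), the natural logarithm of the ratio of summed aerotolerant to
    summed strict-anaerobe abundance, and a keystone score that sums
    cohort-referenced Z-scores of log10 relative abundances of six
    keystone gut species. Includes harmonizing readers for several OTU
    table dialects, phenotype binning of self-reported gastrointestinal
    conditions into healthy, mild, and diseased groups, nonparametric
    cohort comparisons (rank-sum, Kruskal-Wallis, Benjamini-Hochberg
    FDR), a synthetic cohort generator with controllable score
    distributions for testing, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
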