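Package: fdscan
Title: Proteome-Scale Detection of Clade-Specific Functional Divergence
    in Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects amino-acid sites showing radical, clade-specific
    substitution shifts in families of homologous proteins.  For every
    internal node of a per-gene distance tree the two descendant clades
    are contrasted against the remaining outgroup with a Welch-type
    statistic on BLOSUM62 substitution scores; site significance is
    calibrated against alignments simulated under neutral JTT evolution
    with discrete-gamma rate heterogeneity on the same tree, and
    corrected per node with the Benjamini-Hochberg false discovery rate.
    Branch-level calls are aggregated into functional-category and
    species enrichment tests and a clustered enrichment-status heatmap,
    so that lineage-specific shifts in selective constraint can be read
    off whole collections of proteomes.  Includes a synthetic-data
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
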