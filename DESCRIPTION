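Package: dupliscan
Title: Genome-Wide Survey of Evolutionarily Young Gene Duplicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies evolutionarily young paralog pairs in small gene
    families from a genome and its annotation, estimates synonymous divergence
    (Ks) with the Nei-Gojobori (1986) method, screens paralogs for ectopic gene
    conversion with an outgroup-anchored permutation test, delineates
    duplication tracts by anchor-chain alignment of genomic neighborhoods,
    classifies each duplication's structure (complete, partial, chimeric),
    mechanism (DNA- vs RNA-mediated) and genomic geography, and computes
    cohort-level statistics (Williams-corrected G-tests, normalized chromosome
    frequencies with half-event counting, centromere-distance binning, and
    correlation/rank tests). Includes a seeded synthetic-genome simulator that
    plants truth-labelled duplication events so the whole pipeline can be
    validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    data.table,
    ape,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
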