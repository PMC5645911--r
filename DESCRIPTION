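Package: paralogon
Title: Synteny and Parsimony Analysis of Duplicated Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether two paralogous genomic regions
    descend from a single ancestral whole-genome duplication or from
    independent lineage-specific duplications, motivated by the duplicated
    rhodopsin (rho) regions of eels and arowana. Implements microsynteny
    presence/order matrices over a reference gene panel, Dollo-parsimony
    gene-loss counting on a species tree with scenario ranking,
    reciprocal-best-hit ortholog anchoring and macrosynteny dot-plot
    statistics, concatenated-supermatrix maximum-likelihood phylogenetics
    with RELL branch support, sliding-window Nei-Gojobori dN/dS selection
    scans, and a synthetic-genome simulator with truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    rtracklayer,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
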