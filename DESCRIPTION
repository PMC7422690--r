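Package: ampliTags
Title: Dual-Index Barcode Design, Mistag-Aware Demultiplexing and
    Trait-Annotated OTU Summaries for Amplicon Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for taxon-specific amplicon sequencing workflows that
    label samples with dual 8-nucleotide barcodes. Designs barcode sets
    under a chain of combinatorial constraints (balanced composition, no
    homopolymers, no hairpins or heteroduplexes with the attached primer,
    no match to the template consensus flanking the primer site, minimum
    pairwise distance), builds forward-by-reverse tagging grids that leave
    unused combinations so tag jumping (mistagging) becomes observable,
    demultiplexes merged paired reads by exact tag matching, and
    post-processes OTU tables: rare-cluster removal, best-hit taxonomy
    parsing, non-target removal, functional-trait (trophic guild)
    annotation and alpha/beta diversity summaries. Includes a synthetic
    data generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    vegan,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Preprocessing, Microbiome, Metagenomics
RoxygenNote: 7.3.3
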