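Package: mirforge
Title: Small RNA-Seq miRNA Discovery with Hairpin Structural Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for discovering microRNA genes
    from small RNA sequencing libraries: adapter clipping and read collapsing,
    exact genome mapping, annotation-priority categorisation, excision and
    thermodynamic folding of candidate hairpin precursors, a structural filter
    on the miRNA/miRNA* duplex (folding energy, unpaired bases, bulge size,
    asymmetry, 3' overhangs), a dinucleotide-shuffle folding p-value, and a
    catalogue layer that calls known and novel miRNA loci and annotates
    clusters, paralogs, conservation classes, sense/antisense pairs, genomic
    context and isomiR end heterogeneity. Includes a synthetic-data generator
    that plants hairpin loci, decoy non-coding RNAs and sequencing artefacts
    in a toy genome together with a ground-truth manifest, so the whole
    pipeline can be exercised and validated without real libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ShortRead,
    data.table,
    stats,
    utils,
    methods,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
SystemRequirements: ViennaRNA (RNAfold on the PATH) for the default
    RNA-folding engine; a custom engine can be supplied instead.
Config/testthat/edition: 3
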