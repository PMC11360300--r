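Package: ampliso
Title: Targeted Long-Read Amplicon Isoform Discovery for Modular Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of targeted long-read amplicon
    sequencing of a modular multi-isoform locus, modelled on the myeloid
    NRG1 class-VII transcription start site. Provides an exon-level locus
    and transcript data model with a bidirectional isoform nomenclature
    grammar; a seeded nanopore-like amplicon read simulator with
    substitution/indel errors, splice-junction wobble and truncation; a
    bespoke k-mer-seeded splice-aware exon-chain caller with alignment QC
    gates, wobble-aware chain clustering and a high-confidence read-fraction
    filter; open reading frame prediction with poison-exon/premature-stop
    detection, nonsense-mediated decay classification and protein-domain
    annotation; and efficiency-corrected relative qRT-PCR quantification by
    the Pfaffl method, including primer-efficiency estimation from dilution
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    withr,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
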