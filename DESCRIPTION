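Package: rddetect
Title: Detection of RNA-DNA Differences from Matched DNA/RNA Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A filter-cascade pipeline for calling RNA editing sites
    (RNA-DNA differences, RDDs) from matched per-site DNA and RNA pileup
    tables. Sites that are strictly homozygous in genomic DNA but carry a
    confidently supported alternative allele in RNA are passed through a
    set of read-support, quality, strand-bias, splice-proximity and
    edit-ratio filters; surviving sites are strand-corrected into the
    12 transcript-sense substitution types, classified by genic region,
    assessed for coding consequences, and intersected across biological
    replicates into per-tissue common editing sites. A synthetic-data
    module simulates a toy genome, gene models, diploid SNVs and editing
    events with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
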