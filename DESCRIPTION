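Package: promarch
Title: Promoter Architecture Analysis of Transcription-Factor Binding,
    Expression and Chromatin Accessibility
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the promoter-centric binding architecture of
    zinc-finger transcription factors such as ZFX and ZNF711 from ChIP-seq,
    knockdown RNA-seq and NOMe-seq data. Annotates peaks against promoters
    (+/- 2 kb of a TSS), distal enhancers and insulators; classifies CpG-island
    versus non-CpG-island promoters; scans both strands for IUPAC consensus
    motifs and builds TSS-relative positional frequency profiles with
    scrambled-motif null controls; profiles summit-to-TSS offsets and clusters
    promoters into upstream/downstream/bidirectional binding classes;
    integrates binding with differential expression via exact contingency
    statistics; calls nucleosome-depleted regions from GpC methylation
    footprints; and ships a seeded synthetic-data generator that emulates the
    full data structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
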