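Package: gatafam
Title: Comparative Characterization of MED and END GATA-Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative characterization of the MED, END-1 and
    END-3 GATA transcription-factor families across Caenorhabditis species:
    TBLASTN-HSP-guided gene-model stitching with splice-site validation,
    C4 zinc-finger detection and spacing classification, poly-serine and
    Endodermal GATA Domain annotation, pseudogene calling, promoter extraction
    with IUPAC consensus motif scanning and Poisson enrichment statistics,
    serine codon-usage bias testing, microsynteny and tandem-cluster analysis,
    alignment conservation profiling with a p-distance tree check, and a
    seeded synthetic-genome generator that plants every measured feature with
    machine-readable truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
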