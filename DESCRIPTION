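Package: indelscout
Title: Genome-Wide InDel Marker Discovery by Electronic PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers insertion/deletion (InDel) length-polymorphism markers
    from low-coverage resequencing reads by electronic PCR (e-PCR). Designs
    tiling primer pairs over a reference genome with a sliding window, keeps
    pairs that amplify a single product in each of two reference genomes,
    virtually amplifies quality-filtered reads from many samples with a
    mismatch-tolerant matcher, genotypes loci by consensus amplicon length,
    scores markers by polymorphism information content (PIC), classifies them
    by genomic region, selects gel-appropriate marker panels and designs
    validation PCR primers under nearest-neighbor melting-temperature
    constraints. Includes a seeded simulator of diverged genomes, populations
    with planted InDels and sequencing reads for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    methods,
    rtracklayer,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stringi,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
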