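Package: himera
Title: Detection and Quantification of Bracovirus Circle Integrations from
    Chimeric Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify chromosomal integration of
    polydnavirus (bracovirus) DNA circles into a lepidopteran host genome
    from wasp-host chimeric sequencing reads. Provides a synthetic-data
    generator with full ground truth (proviral segments flanked by direct
    repeat junctions, host integration motifs split into J1/J2, circle
    excision and HIM-mediated integration with controlled junction
    microhomology), a four-filter chimeric-read classifier with PCR
    deduplication, integration-event calling and per-million-read
    normalisation, empirical J1/J2 delineation and a random-chimera
    microhomology null, motif-based annotation of HIM-mediated and
    rearranged duplications, and a Poisson window test for spatial
    randomness of integration sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    rtracklayer,
    S4Vectors,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
SystemRequirements: BLAST+ (makeblastdb, blastn) for the alignment-based
    pipeline steps; precomputed tabular alignments can be supplied instead.
Config/testthat/edition: 3
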