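Package: couplonscan
Title: Spatiotemporal Analysis of Bacterial Regulons and Couplons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the joint control of bacterial genes by
    nucleoid-associated proteins (NAPs), global transcription factors and RNA
    polymerase sigma factors. Builds couplons (intersections of NAP or global-TF
    regulons with sigma-factor regulons) from a regulatory-network table,
    quantifies their spatial organisation on the circular chromosome with
    sliding-window resampling Z-scores, summarises their growth-phase expression
    as unit-normalised temporal profiles with remapping uncertainty envelopes,
    and profiles promoter GC content around transcription start sites. Includes
    a synthetic-data generator that plants spatial clustering, regulon overlap
    and temporal programs so every stage of the pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
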