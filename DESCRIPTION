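Package: pairspace
Title: Genome Arithmetic for Chromatin Interactions in BEDPE Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit of composable operations on chromatin-interaction
    (BEDPE) files and binned contact matrices from HiC and HiChIP
    experiments. Builds candidate element pairs from BED files under TAD
    and distance constraints, extracts loops from contact matrices with a
    distance-decay-free 0-1 "inherent" score, queries matrix values onto
    BEDPE rows (center/max/sum/mean, two-sample deltas), performs 2D set
    operations (intersect, union, cluster, annotate), and computes
    profile matrices (contact windows, virtual 4C, aggregate peak
    analysis). Supports raw, counts-per-million and spike-in (AQuA)
    numeric spaces, ships a deterministic HiChIP-like synthetic-data
    generator, and exposes every operation through a pipe-friendly
    command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
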