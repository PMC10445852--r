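Package: annotqc
Title: Genome Annotation QC, Chimera Splitting and Two-Genome Comparative Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control and comparative-genomics pipeline for a
    chromosome-scale insect genome annotation project. Implements assembly
    contiguity metrics (N50/L50/auN), scaffold length filtering, transcript
    contig post-processing (end trimming, DUST-style low-complexity masking,
    six-frame ORF discovery, consistent read-pair coverage, chimeric contig
    splitting and strand orientation), evidence-based retention rules for
    transcript and protein alignments, the sequential gene-model filtering
    cascade (repeat/TE, UTR-ratio and intronless evidence rules), reciprocal
    best-hit orthology, greedy macrosynteny chaining with circos-style links,
    paralog clustering and family-expansion tables, an ortholog CDS-length
    log-log regression, and satellite/mitochondrial copy scanning by iterative
    masked local alignment. Ships a deterministic synthetic-data generator
    that produces every input with ground truth attached so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
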