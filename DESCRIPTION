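Package: circchar
Title: Characterization of Circular RNAs from Back-Spliced Junction Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream characterization of circular RNAs (circRNAs) called
    from back-spliced junction reads. Starting from per-sample junction
    tables and a genome annotation, the package classifies junctions into
    exonic and intronic circRNAs against union-merged gene models, builds a
    consolidated multi-sample catalog with counts-per-million normalization
    and read-count filters, compares biological replicates and developmental
    stages, computes genomic features (exon position within the parent gene,
    spanned exon count and length, flanking versus control intron lengths,
    repeat coverage, inverted repeats in flanking introns), summarizes
    alternative circularization, and runs the associated statistics:
    hypergeometric term enrichment with false-discovery-rate q-values,
    stage-wise differential expression by t-test, and circRNA-parent-gene
    expression correlation tested through the t-distribution of Pearson's r.
    A self-contained synthetic-data generator with a planted ground truth
    makes every pipeline stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
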