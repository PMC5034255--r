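Package: consplice
Title: Consensus-Annotation Alternative Splicing Analysis for Gene-Dense Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies alternative splicing events in gene-dense (fungal)
    genomes against a per-gene consensus exon annotation. Provides
    region-restricted genome fragmentation and back-projection for
    per-gene transcript assembly workflows, transcript filtering (strand,
    junction support, minimum open reading frame), primitive event calling
    (intron retention, exon skipping, alternative 5'/3' splice sites) and
    composite event calling (mutually exclusive exons, multiple alternative
    splice sites) with three-level counting and coding/UTR/reading-frame
    context, splice-junction cluster analysis with singleton removal,
    time-course isoform-switch detection over developmental stages, and
    functional-impact assessment from domain and localization predictor
    tables. A deterministic synthetic-data generator with planted ground
    truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
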