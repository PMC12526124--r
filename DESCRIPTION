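Package: regcircuit
Title: Enhancer Landscapes, TF Co-Binding and Core Regulatory Circuits from ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop pipeline for regulatory-genomics integration in a
    two-condition design: ROSE-style enhancer stitching and super-enhancer
    calling from H3K27ac peaks, condition-unique (differential) enhancer
    derivation, rule-based four-state chromatin classification of
    transcription-factor binding sites, binned Fisher co-binding statistics,
    enhancer-to-gene assignment (nearest-TSS and curated-interaction modes),
    upregulation-filtered transcriptional regulatory networks, preranked
    running-sum and hypergeometric gene-set enrichment, and protein-protein
    interaction subgraph analysis with hub-centred core-regulatory-circuit
    extraction. Ships a synthetic-data generator with planted ground truth so
    every stage is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
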