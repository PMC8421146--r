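Package: junctionscan
Title: Off-Target and Editing-Outcome Analysis from CRISPR Translocation
    Junction Libraries
Version: 0.1.0
Authors@R: person("PEM-seq", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Junction-level analysis of CRISPR-Cas9 genome editing from
    translocation-capture sequencing (PEM-seq style) junction tables:
    genome-wide enumeration of guide-homologous candidate sites with
    mismatch and PAM classification, off-target hotspot calling from
    junction enrichment, classification of editing outcomes (indels,
    large deletions, off-target and general translocations, plasmid
    integrations) with efficiency and genome-instability metrics,
    consensus and PAM-composition statistics, a small convolutional
    network for ranking candidate off-target sites by sigmoid score,
    and a synthetic-data generator that plants homologous off-target
    sites and simulates junction tables with known outcome proportions
    so the whole pipeline is testable without deposited libraries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
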