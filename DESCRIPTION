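Package: holoscope
Title: Reaction-Level Metatranscriptomics and Metabolic Complementarity for Host-Microbiome Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for holobiont meta-omics experiments in which a
    host organism carries a mixed bacterial community whose members each have a
    genome-scale metabolic network. Per-gene metatranscriptome counts are
    aggregated into metabolic-reaction space across metagenomic bins, bin-level
    transcriptomic activity profiles select the active community members, and a
    negative-binomial Wald engine tests reactions (or genes) under one- and
    two-factor designs with interaction terms, followed by pathway-level
    summarisation. A network-expansion ("scope") engine computes metabolite
    producibility from a seed medium, community-level producibility under
    mixed-bag sharing, and the in-silico added value of the community for the
    host. GC-MS feature-table statistics (blank subtraction, presence
    filtering, dry-weight and log10 normalisation, Welch tests, annotation
    tiering) and a synthetic-data generator with recorded ground truth for
    every stage complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    knitr
Config/testthat/edition: 3
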