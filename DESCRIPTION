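Package: trntopo
Title: Topology and Motif Analysis of Transcriptional Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly, filtering and topological analysis of evidence-annotated
    transcriptional regulatory networks (TF -> target gene edge lists with
    binding/expression evidence, regulation signs, environmental condition tags
    and literature support). Provides evidence-based sub-network extraction
    (binding, expression, union, intersection), density and Venn summaries,
    reference-support statistics, in-/out-degree tables and distributions,
    chi-squared merging of in-degrees into functional bins, a directed triad
    census over the 13 connected 3-node classes, degree-preserving
    edge-switching randomization, triad significance profiles, a seeded
    synthetic network generator with full bookkeeping, and a deterministic
    end-to-end analysis pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
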