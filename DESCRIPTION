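Package: bzipscan
Title: Characterization of Plant bZIP Transcription Factor Families
Version: 0.1.0
Authors@R: person("bzipscan", "maintainers", email = "bzipscan@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of basic leucine zipper
    (bZIP) transcription factor families in plants. Locates the bZIP domain
    architecture (16-residue basic region with the invariant N-x7-R/K motif,
    hinge, and leucine-zipper heptads with g/a/b/c/d/e/f register), assigns
    DNA-binding specificity groups from basic+hinge signature templates,
    predicts leucine-zipper dimerization properties from a/d residue content
    and electrostatic g-to-e' pair typing, types intron splicing phases within
    the domain, classifies homolog pairs as tandem or segmental duplications by
    collinear anchor chaining, and applies FPKM expression filters. Includes a
    fully seeded synthetic-data generator that plants ground truth for every
    stage, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
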