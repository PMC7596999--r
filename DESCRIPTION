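Package: IsoCollapse
Title: Error-Aware Collapsing and Merging of Long-Read Transcript Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Collapses genome-mapped long RNA reads (Iso-Seq, Nanopore) into
    non-redundant transcript models with error-aware splice-junction calling:
    alignment quality and local density error (LDE) filtration, wobble-tolerant
    exon-chain grouping in capped and no-cap modes, and mismatch-profile based
    splice-junction ranking. Merges annotations from multiple sources with
    per-source collapse modes and feature priorities, traces read support
    through arbitrary pipeline chains, filters fragment and low-support models,
    and computes diagnostic statistics: the Degradation Signature (an estimate
    of the fraction of reads from 5' degraded RNA), splice-junction wobble
    against a reference annotation, read-jumble detection between pipelines,
    and ORF/NMD transcript labelling. Includes a deterministic simulator of
    toy genomes and spliced long reads with controlled degradation, splice-
    flanking error density and genomic poly-A artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
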