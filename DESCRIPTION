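Package: tridram
Title: Joint Analysis of 3D Genome Contacts, Chromatin Accessibility and
    DNA Methylation from Single Molecules
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-omic assays that read out chromosome
    conformation, GpC accessibility (NOMe footprinting) and endogenous CpG
    methylation from the same bisulfite-converted, proximity-ligated
    molecules. Implements pre-alignment chimeric-read splitting at
    converted DpnII ligation junctions, restriction fragment-end (fend)
    assignment and contact deduplication, NOMe cytosine-context
    classification, coverage-filtered methylation pileups, spike-in
    bisulfite conversion QC, strand-aware metaprofiles, a single-molecule
    long-range co-accessibility assay (anchoring, window filtering,
    read-pair merging, k-means clustering, Fisher exact dependence
    testing, randomized controls), and contact-level statistics
    (distance-decay curves, insulation and TAD boundary calling, rescaled
    TAD pileups, A/B compartment eigenvectors and compartment strength,
    aggregate pairwise contact enrichment, per-pair scores, and
    peak-to-gene association). A seeded synthetic-data generator with
    known ground truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
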