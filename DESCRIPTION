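Package: gapstitch
Title: Long-Read Scaffolding and Gap Filling of Genome Assemblies
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scaffolds and gap-fills an existing genome assembly using long
    reads (Oxford Nanopore or PacBio CLR) or the contigs of a second assembly.
    Joining sequences are aligned to the input contigs with minimap2, filtered
    to long "proper" alignments that reach contig ends within a bounded
    overhang, and bundled into supported links between contig ends. A
    side-typed contig graph is resolved into linear scaffold paths by
    collapsing linear stretches into super-nodes, iteratively popping
    haplotype bubbles (keeping the longest branch), temporarily removing
    repeat nodes, breaking ambiguous branches, and re-inserting repeats with
    sequence duplication where spanning evidence exists. Spanned gaps are
    filled with consensus "patch" sequences built from the supporting read
    intervals, patches are re-anchored to the flanking contig ends (trimming
    locally mis-assembled tips), and short contigs uniquely contained in a
    patch are absorbed. Includes a synthetic-data generator (genomes with
    interspersed repeats, fragmented contigs, error-bearing long reads) and
    truth-based evaluation utilities (coverage, mis-joins, patch error rate,
    N50/NG50).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
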