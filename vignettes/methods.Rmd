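---
title: "Scaffolding and gap filling with long reads: the gapstitch method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding and gap filling with long reads: the gapstitch method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapstitch)
```

## The problem

Many genome assemblies built from short reads (or early long-read data)
capture most of the non-repetitive sequence of a genome but remain
fragmented at repeats. Re-assembling from scratch is often impractical;
a cheaper upgrade path is to *re-scaffold* the existing contigs with
10--30x of additional long reads (Oxford Nanopore or PacBio CLR), or with
the contigs of a second assembly of the same or a closely related genome.
`gapstitch` implements this upgrade: it orders and orients the input
contigs using long-range linking information and, unlike pure
scaffolders, also *fills every spanned gap* with a consensus sequence
("patch") computed from the linking reads, so its output scaffolds are
gapless contigs wherever the evidence allows.

## The method

Let $C = \{C_k\}$ be the input contigs and $J = \{J_i\}$ the joining
sequences. The pipeline is:

1. **Alignment.** All $J_i$ are mapped to $C$ with minimap2 (preset
   `map-ont`, `map-pb` or `asm20` according to the data type); a
   precomputed PAF may be supplied instead.
2. **Proper alignments.** Only the best alignments are kept (per-query
   dominance by residue matches; an alignment loses when half of its query
   interval is covered by a better one). An alignment is *proper* when its
   block is at least `min_aln_len` (default 5000 bp) and, on every side
   where the read continues past it toward a contig end, the unaligned
   contig stub is at most `max_overhang` (default 1000 bp). The length
   floor removes short repeat-induced matches; the overhang allowance
   exists because contig ends frequently carry local mis-assemblies --
   the very reason the original assembler stopped there -- and the method
   can repair them while joining.
3. **Links and bundles.** A join aligning properly to two or more contigs
   contributes one link per *adjacent* pair of its alignments along the
   read; joins touching a single contig are discarded. Concordant links
   between the same pair of contig ends are bundled; with deep read
   coverage a bundle must have `min_support >= 2` (one suffices in `asm`
   mode). The bundle's gap estimate is the median of member estimates
   (robust to one aberrant spanning read). Skip-one pairs (alignments
   $i$ and $i+2$ of the same read) are additionally bundled as repeat
   flank-pairing *evidence*; they never become scaffold edges or patches
   (see "Repeats" below for why they are needed).
4. **Patches.** For each bundle the junction interval of every supporting
   read is extracted (the estimated gap plus up to `max_overhang` of
   contig-end replacement plus an `anchor_bp = 200` anchor on each side).
   In read modes a template-plus-majority-vote pileup consensus is
   computed; in `asm` mode the single supporting interval is used verbatim
   and no consensus is computed. Each patch is then re-aligned to its two
   flanking contig ends; the anchor alignments fix the trim points
   (how much of each possibly mis-assembled contig tip the patch
   replaces) and patches that fail to anchor at 95% identity are demoted
   to plain N-gaps (the scaffold link is kept).
5. **Graph resolution.** Contigs become nodes of a side-typed undirected
   graph whose edges are the anchored bundles. Resolution: collapse
   maximal runs of *linear* nodes (at most one edge per side) into
   super-nodes; pop *bubbles* (two or more parallel branch nodes between
   a shared source end and sink end, typically haplotype variants) by
   keeping the branch of greatest total length, iterating with collapsing
   until a fixed point; mark nodes with two or more edges on *both* sides
   as *repeats*, remove them while recording their edges; re-collapse;
   delete all edges at any side still carrying two or more edges (one
   global scan over a frozen degree snapshot); the remaining components
   are simple paths.
6. **Repeat re-insertion.** Each removed repeat is re-inserted -- with its
   sequence duplicated once per insertion -- where its recorded edges pair
   the two flanks of a junction on opposite repeat sides *and* the pairing
   itself is evidenced, either by a direct flank-to-flank edge (an
   internal path junction) or by a skip-one evidence bundle joining two
   free path ends. Pairings are chosen greedily by summed support, each
   flank used once. Repeats with no evidenced pairing are emitted
   standalone: the method only resolves repeats completely spanned by
   joining sequences with long anchors in the surrounding unique sequence.
7. **Emission and absorption.** Paths are written as scaffold FASTA (with
   patches in place and unfilled gaps as N-runs of the clamped estimate),
   AGP v2.1 and a junction report. Finally, standalone contigs shorter
   than the longest patch that align to exactly one patch with more than
   95% identity over more than 95% of their length are spliced into that
   patch and removed from the output -- they are redundant copies of
   sequence now present in a patch.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_aln_len` | 5000 bp | minimum proper-alignment block; contigs shorter than this cannot be scaffolded. 2500 bp is a reasonable tuning for smaller plant genomes at the cost of more aggressive joins. |
| `max_overhang` | 1000 bp | bound on the unaligned contig stub at a touched end; also bounds how much of a mis-assembled tip a patch may replace. |
| `min_support` | 2 (reads) / 1 (`asm`) | links per bundle; more than one spanning read is demanded under deep coverage. |
| `anchor_bp` | 200 bp | flank retained on each side of a junction interval for re-anchoring QC. Not a sensitive choice; it only needs to be long enough for an unambiguous 95%-identity anchor. |

The input assembly should be relatively contiguous: the pipeline warns
when the assembly N90 falls below `min_aln_len` (the guideline is an
N90 above 10 kb).

## Numerical choices and edge cases

* Coordinates are 0-based half-open (PAF convention) everywhere inside
  the package; only the AGP writer converts to 1-based inclusive.
* Consensus: the template is the member interval of median length (lower
  median); members are globally aligned to it and each template column is
  decided by majority vote with deletion as a voting symbol, ties keeping
  the template symbol. Insertions relative to the template are not voted,
  so the consensus length never exceeds the template's; the residual
  patch error is dominated by template deletions (about a third of the
  read error rate), still several-fold below any single read. Support is
  capped at 20 members per junction (those closest to the template
  length), which is ample for majority voting and bounds the alignment
  cost at high coverage.
* Members whose alignment to the template drops below 60% identity are
  discarded as mis-extracted; if support then falls below `min_support`
  the junction is demoted to an N-gap.
* Negative gap estimates (overlapping contig ends) are realised through
  the trims: the patch core may be empty and the overlap is removed from
  the flanking contigs, bounded by `max_overhang` per side; larger
  overlaps demote the junction.
* Ties are broken deterministically throughout (bubble winner by
  lexicographically smallest member id, repeat pairing by a
  direction-independent flank key), so identical inputs reproduce
  identical outputs byte for byte; the alignment stage is cached by a
  content hash of its inputs.
* All-linear cycles in the graph (circular structures the method does not
  model) are opened deterministically at the smallest member contig id;
  same-contig self-edges are dropped.
* Unfilled gaps are written as N-runs of the estimated size clamped to
  [100, 1e6] bp, since AGP requires a positive gap length.

## Design choices where the design was open

* **"Longest" bubble branch** is read as greatest *total* branch length
  (member lengths plus non-negative gap estimates), not longest single
  node, so a two-contig branch can beat a longer single contig -- this is
  the reading consistent with collapsing branches into super-nodes first.
* **"Best alignments"** is defined as per-query interval dominance by
  residue matches with deterministic tie-breaks; primary/secondary flags
  are not consulted (the PAF may lack them).
* **Block length** is the quantity compared against `min_aln_len`
  (query and target spans differ from it only through indels at these
  error rates).
* **Repeat pairing evidence.** Adjacent-pair linking alone can never
  produce the direct flank-to-flank edge that justifies threading a path
  through a repeat: a read spanning flank--repeat--flank yields only the
  two adjacent links. The skip-one evidence bundles restore exactly the
  information carried by reads that span the whole repeat with long
  unique anchors, and nothing more; they are deliberately excluded from
  scaffolding edges so that transitive links cannot inflate the graph.
* **Absorption candidates** are restricted to contigs that ended up
  standalone: absorbing a contig that is a member of a scaffold path
  would tear the path and break conservation accounting.

## What the synthetic data emulates -- and what it does not

`simulate_genome()` produces an i.i.d. uniform ACGT background with
optional planted repeat copies at a stated identity;
`fragment_genome()` tiles it into gapped, partially reverse-complemented
contigs with optional shuffled-tip perturbation (to exercise overhang
trimming); `simulate_reads()` draws uniform read starts, log-normal
lengths (sdlog 0.25) and i.i.d. substitution/insertion/deletion errors in
1:1:1 ratio. All generators are bit-reproducible under a fixed seed.

Real data differ in ways the generator does not model: biased base
composition, homopolymer-concentrated ONT/PacBio errors, chimeric reads,
adapter remnants, heterozygosity (bubbles are exercised at graph level,
not through diploid simulation), and nested repeat families. A green
end-to-end test therefore establishes that the machinery is correct on
its stated model -- exact recovery of contig order, orientation and gap
sequence when the information is present in the reads -- not that
real-genome accuracy will match the simulation.

## Known limitations

* Repeats are duplicated at most once per evidenced flank pairing; runs
  of two or more distinct collapsed repeats between unique anchors are
  not resolved.
* Pre-existing mis-assemblies in contig *interiors* are neither detected
  nor broken; only tips within `max_overhang` are repaired.
* The pileup consensus is template-anchored; polishing with an external
  tool can further reduce the residual patch error.
* Whole-assembly polishing and QV estimation are out of scope.
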