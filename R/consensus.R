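# Consensus gap patches: build, re-anchor, absorb contained contigs.
#
# Each bundled edge carries the junction interval of every supporting read
# (gap plus up to max_overhang of contig-end replacement plus an anchor on
# each side). In read modes the patch is a template + majority-vote pileup
# consensus of those intervals; when joining with another assembly the
# single supporting interval is used verbatim and no consensus is computed.

consensus_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                           baseOnly = FALSE)
}

# Template + majority-vote pileup consensus of nucleotide strings.
# The template is the interval of median length (lower median; ties broken
# by order of appearance, which callers make deterministic). Every other
# interval is globally aligned to the template; each template column
# receives one symbol per interval (a base or "-", deletion being a voting
# symbol) and the majority wins, ties keeping the template symbol.
# Insertions relative to the template are not voted: the consensus is
# template-anchored, so its length never exceeds the template's. Residual
# consensus error is therefore dominated by template deletions
# (~ error_rate/3), still several-fold below the raw read error.
pileup_consensus <- function(seqs) {
  n <- length(seqs)
  if (n == 1L) return(seqs[[1L]])
  if (length(unique(seqs)) == 1L) return(seqs[[1L]])
  lens <- nchar(seqs)
  ord <- order(lens)
  t_idx <- ord[ceiling(n / 2)]  # lower median for even n
  template <- seqs[[t_idx]]
  tlen <- nchar(template)
  votes <- matrix("", nrow = n, ncol = tlen)
  votes[t_idx, ] <- strsplit(template, "")[[1L]]
  others <- setdiff(seq_len(n), t_idx)
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs[others]), Biostrings::DNAString(template),
    type = "global", substitutionMatrix = consensus_submat(),
    gapOpening = 3, gapExtension = 1)
  for (j in seq_along(others)) {
    i <- others[j]
    pat <- strsplit(as.character(Biostrings::alignedPattern(alns[j])), "")[[1L]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(alns[j])), "")[[1L]]
    keep <- sub != "-"  # insertions relative to the template are skipped
    votes[i, ] <- pat[keep]
  }
  # per-column majority, template symbol wins ties
  out <- character(tlen)
  tsyms <- votes[t_idx, ]
  for (c in seq_len(tlen)) {
    tab <- sort(table(votes[, c]), decreasing = TRUE)
    top <- names(tab)[tab == tab[1L]]
    sym <- if (tsyms[c] %in% top) tsyms[c] else sort(top)[1L]
    out[c] <- if (sym == "-") "" else sym
  }
  paste(out, collapse = "")
}

#' Build a consensus patch for a bundled edge
#'
#' Extracts each supporting read's junction interval (reverse-complemented
#' when the read traverses the junction against the bundle's canonical
#' orientation) and computes their pileup consensus; in `asm` mode the
#' single supporting interval is used verbatim. Members whose global
#' alignment to the template falls below 60% identity are discarded as
#' mis-extracted; if fewer than `min_support` members remain the bundle is
#' demoted to an unfilled gap (`NULL` is returned and the scaffold link is
#' kept with an N-gap).
#'
#' @param bundle one row of the [bundle_links()] data.frame.
#' @param reads named [Biostrings::DNAStringSet] of the joining sequences.
#' @param mode `"ont"`, `"pbclr"` or `"asm"`.
#' @param min_support minimum members after QC.
#' @param max_members consensus support cap; the members closest in length
#'   to the template are kept (default 20).
#' @return a list `(seq, support)` or `NULL` when demoted.
#' @export
build_patch <- function(bundle, reads, mode = c("ont", "pbclr", "asm"),
                        min_support = 2, max_members = 20) {
  mode <- match.arg(mode)
  mem <- bundle$members[[1L]]
  keep <- mem$rend - mem$rstart > 0 & mem$join_id %in% names(reads)
  mem <- mem[keep, , drop = FALSE]
  if (nrow(mem) == 0L) return(NULL)
  seqs <- vapply(seq_len(nrow(mem)), function(i) {
    s <- substr(as.character(reads[[mem$join_id[i]]]),
                mem$rstart[i] + 1L, mem$rend[i])
    if (mem$flipped[i]) revcomp(s) else s
  }, "")
  if (mode == "asm") {
    # no consensus: the single supporting interval, verbatim
    i <- order(nchar(seqs), mem$join_id)[ceiling(length(seqs) / 2)]
    return(list(seq = seqs[[i]], support = length(seqs)))
  }
  # deterministic member order, then cap support near the template length
  ord <- order(mem$join_id, mem$rstart)
  seqs <- seqs[ord]
  ids <- mem$join_id[ord]
  if (length(seqs) > max_members) {
    med <- sort(nchar(seqs))[ceiling(length(seqs) / 2)]
    sel <- order(abs(nchar(seqs) - med), ids)[seq_len(max_members)]
    seqs <- seqs[sort(sel)]
    ids <- ids[sort(sel)]
  }
  if (length(seqs) > 1L && length(unique(seqs)) > 1L) {
    lens <- nchar(seqs)
    t_idx <- order(lens)[ceiling(length(seqs) / 2)]
    template <- seqs[[t_idx]]
    qc <- vapply(seq_along(seqs), function(i) {
      if (i == t_idx) return(1)
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(template),
        type = "global", substitutionMatrix = consensus_submat(),
        gapOpening = 3, gapExtension = 1)
      aln_identity(a)
    }, 0)
    seqs <- seqs[qc >= 0.6]
  }
  if (length(seqs) < min_support) return(NULL)
  list(seq = pileup_consensus(seqs), support = length(seqs))
}

# Oriented flank of a contig facing a junction. side is the contig end at
# the junction; the returned string reads toward the junction.
oriented_flank <- function(contig_seq, side, w) {
  s <- as.character(contig_seq)
  n <- nchar(s)
  w <- min(w, n)
  if (side == "end") substr(s, n - w + 1L, n) else revcomp(substr(s, 1L, w))
}

anchor_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE)
}

#' Re-anchor patches on their flanking contigs
#'
#' Aligns each patch back to the two contig ends it joins and fixes the
#' junction coordinates: `left_trim`/`right_trim` report how many bases of
#' each contig end the patch replaces (local mis-assemblies at contig tips,
#' bounded by `max_overhang`), and the patch sequence is cut down to the
#' bases strictly between the two anchor alignments. Patches failing to
#' anchor on both flanks with at least `min_identity` over the anchor are
#' demoted to unfilled gaps, as are junctions whose anchors overlap by more
#' than the trims can absorb.
#'
#' @param patches named list of patches (`seq`, `support`) keyed by
#'   bundle id; `NULL` entries (already demoted) pass through.
#' @param bundles the [bundle_links()] data.frame the patches belong to.
#' @param contigs named [Biostrings::DNAStringSet] of the assembly.
#' @param max_overhang maximum contig-end replacement in bp.
#' @param anchor_bp anchor length used at extraction time.
#' @param min_identity minimum anchor identity (default 0.95).
#' @return a named list of anchored patches
#'   (`seq`, `left_trim`, `right_trim`, `support`, `status = "patch"`) with
#'   `NULL` for demoted junctions.
#' @export
realign_patches <- function(patches, bundles, contigs, max_overhang = 1000,
                            anchor_bp = 200, min_identity = 0.95) {
  out <- stats::setNames(vector("list", nrow(bundles)), bundles$bundle_id)
  w <- anchor_bp + 2 * max_overhang
  for (i in seq_len(nrow(bundles))) {
    bid <- bundles$bundle_id[i]
    p <- patches[[bid]]
    if (is.null(p) || is.null(p$seq)) next
    pseq <- p$seq
    plen <- nchar(pseq)
    if (plen == 0L) next
    la <- anchor_one(oriented_flank(contigs[[bundles$contig_a[i]]],
                                    bundles$side_a[i], w),
                     pseq, left = TRUE, anchor_bp, min_identity, w)
    ra <- anchor_one(oriented_flank(contigs[[bundles$contig_b[i]]],
                                    bundles$side_b[i], w),
                     pseq, left = FALSE, anchor_bp, min_identity, w)
    if (is.null(la) || is.null(ra)) next
    left_trim <- la$trim; right_trim <- ra$trim
    core_start <- la$cut + 1L
    core_end <- ra$cut - 1L
    if (core_start > core_end + 1L) {
      # anchors overlap on the patch: contig ends overlap; realise the
      # merge through extra trimming, bounded by max_overhang per side
      extra <- core_start - core_end - 1L
      take_r <- min(extra, max_overhang - right_trim)
      right_trim <- right_trim + take_r
      extra <- extra - take_r
      if (extra > 0) {
        take_l <- min(extra, max_overhang - left_trim)
        left_trim <- left_trim + take_l
        extra <- extra - take_l
      }
      if (extra > 0) next  # overlap exceeds what trims may absorb: demote
      core_start <- 1L; core_end <- 0L
    }
    if (left_trim > max_overhang || right_trim > max_overhang) next
    out[[bid]] <- list(
      seq = if (core_end >= core_start) substr(pseq, core_start, core_end)
            else "",
      left_trim = left_trim, right_trim = right_trim,
      support = p$support, contig_a = bundles$contig_a[i],
      side_a = bundles$side_a[i], status = "patch")
  }
  out
}

# Anchor one patch end on an oriented contig flank. Returns the trim (bp of
# contig end replaced by the patch) and the cut position on the patch
# (last patch base matching the contig for left = TRUE, first for FALSE),
# or NULL when the anchor fails QC.
anchor_one <- function(flank, pseq, left, anchor_bp, min_identity, w) {
  flen <- nchar(flank)
  plen <- nchar(pseq)
  reg_len <- min(plen, w + anchor_bp)
  # oriented_flank() reads toward the junction for both roles, so the
  # right side is the left problem in mirrored (reverse-complemented)
  # patch coordinates
  region <- if (left) substr(pseq, 1L, reg_len)
            else revcomp(substr(pseq, plen - reg_len + 1L, plen))
  a <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(flank), Biostrings::DNAString(region),
    type = "local", substitutionMatrix = anchor_submat(),
    gapOpening = 4, gapExtension = 1)
  span <- Biostrings::nchar(Biostrings::alignedPattern(a))
  if (span < min(anchor_bp, flen) * 0.5) return(NULL)
  if (aln_identity(a) < min_identity) return(NULL)
  p_end <- IRanges::end(Biostrings::pattern(a))   # on the oriented flank
  s_end <- IRanges::end(Biostrings::subject(a))   # on the (oriented) region
  trim <- flen - p_end
  if (left) {
    list(trim = trim, cut = s_end)
  } else {
    # map back from the reversed region to patch coordinates
    cut <- plen - s_end + 1L
    list(trim = trim, cut = cut)
  }
}

#' Absorb short contigs uniquely contained in patches
#'
#' Candidate contigs (standalone contigs shorter than the longest patch)
#' are aligned to every patch; a contig aligning to exactly one patch with
#' more than 95% identity over more than 95% of its length has its sequence
#' spliced into that patch, replacing the matching patch interval, and is
#' removed from the final output. Contigs contained in two or more patches
#' are left untouched (the containment must be unique).
#'
#' @param patches named list of anchored patches (see [realign_patches()]).
#' @param contigs named [Biostrings::DNAStringSet].
#' @param candidate_ids ids eligible for absorption (standalone contigs).
#' @param min_identity,min_coverage the 95/95 containment thresholds
#'   (strict inequalities).
#' @return list `(patches, removed)` with updated patch sequences and the
#'   `data.frame` of absorbed contigs (`contig`, `patch_id`).
#' @export
absorb_contained_contigs <- function(patches, contigs, candidate_ids,
                                     min_identity = 0.95,
                                     min_coverage = 0.95) {
  removed <- data.frame(contig = character(0), patch_id = character(0),
                        stringsAsFactors = FALSE)
  live <- names(patches)[!vapply(patches, is.null, TRUE)]
  if (length(live) == 0L || length(candidate_ids) == 0L)
    return(list(patches = patches, removed = removed))
  plens <- vapply(live, function(k) nchar(patches[[k]]$seq), 0)
  maxp <- max(plens)
  cand <- candidate_ids[as.numeric(Biostrings::width(contigs[candidate_ids]))
                        < maxp]
  hits <- list()
  for (cid in sort(cand)) {
    cseq <- as.character(contigs[[cid]])
    clen <- nchar(cseq)
    chits <- NULL
    for (k in live) {
      if (plens[[k]] < min_coverage * clen) next
      best <- NULL
      for (orient in c("+", "-")) {
        q <- if (orient == "+") cseq else revcomp(cseq)
        a <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), Biostrings::DNAString(patches[[k]]$seq),
          type = "local", substitutionMatrix = anchor_submat(),
          gapOpening = 4, gapExtension = 1)
        cov <- Biostrings::nchar(Biostrings::pattern(a)) / clen
        idn <- aln_identity(a)
        if (cov > min_coverage && idn > min_identity &&
            (is.null(best) || idn > best$idn)) {
          best <- list(patch = k, orient = orient, idn = idn,
                       s_start = IRanges::start(Biostrings::subject(a)),
                       s_end = IRanges::end(Biostrings::subject(a)))
        }
      }
      if (!is.null(best)) chits <- c(chits, list(best))
    }
    if (length(chits) == 1L) hits[[cid]] <- chits[[1L]]
  }
  # splice, processing hits within a patch right-to-left
  if (length(hits) > 0L) {
    byp <- split(names(hits), vapply(hits, `[[`, "", "patch"))
    for (k in names(byp)) {
      cids <- byp[[k]]
      cids <- cids[order(-vapply(hits[cids], `[[`, 0L, "s_start"))]
      for (cid in cids) {
        h <- hits[[cid]]
        seq <- patches[[k]]$seq
        ins <- if (h$orient == "+") as.character(contigs[[cid]])
               else revcomp(as.character(contigs[[cid]]))
        patches[[k]]$seq <- paste0(substr(seq, 1L, h$s_start - 1L), ins,
                                   substr(seq, h$s_end + 1L, nchar(seq)))
        removed <- rbind(removed, data.frame(contig = cid, patch_id = k,
                                             stringsAsFactors = FALSE))
      }
    }
  }
  list(patches = patches, removed = removed)
}
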