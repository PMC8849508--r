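# Truth-based evaluation of scaffolding results.

#' Evaluate scaffolds against a simulation truth
#'
#' Computes contiguity statistics from the scaffold sequences and, when the
#' scaffold paths are supplied, junction-level correctness: a mis-join is a
#' scaffold junction whose two contigs are not adjacent in the truth
#' placement or meet in the wrong relative orientation. Genome coverage is
#' the fraction of the genome covered by the core placements of scaffolded
#' contigs plus the gaps of correct junctions. Patch error rate aligns each
#' patch to its true genome window and averages `1 - identity`.
#'
#' @param scaffolds named [Biostrings::DNAStringSet] of scaffold sequences
#'   (or a FASTA path).
#' @param truth truth object from the simulators.
#' @param paths optional list of chains (scaffold member paths) as produced
#'   by [resolve_graph()] / [scaffold_run()].
#' @param patches optional named list of anchored patches keyed by
#'   bundle id.
#' @return a list report: `n_scaffolds`, `total_bp`, `max_len`, `n50`,
#'   `ng50`, and (with `paths`) `n_junctions`, `misjoins`, `coverage`, and
#'   (with `patches`) `patch_error_rate`.
#' @export
evaluate_scaffolds <- function(scaffolds, truth, paths = NULL,
                               patches = NULL) {
  if (is.character(scaffolds)) scaffolds <- read_fasta(scaffolds)
  lens <- as.numeric(Biostrings::width(scaffolds))
  rep <- list(
    n_scaffolds = length(scaffolds),
    total_bp = sum(lens),
    max_len = if (length(lens)) max(lens) else 0,
    n50 = n50(lens),
    ng50 = ng50(lens, truth$genome_len))
  if (!is.null(paths) && !is.null(truth$contigs)) {
    tc <- truth$contigs
    idx <- stats::setNames(seq_len(nrow(tc)), tc$id)
    torient <- stats::setNames(tc$orient, tc$id)
    n_j <- 0L; bad <- 0L
    covered <- IRanges::IRanges()
    for (ch in paths) {
      m <- ch$members
      known <- m$id %in% tc$id
      covered <- c(covered, IRanges::IRanges(
        start = tc$start[idx[m$id[known]]] + 1L,
        end = tc$end[idx[m$id[known]]]))
      if (nrow(m) < 2L) next
      for (k in seq_len(nrow(m) - 1L)) {
        n_j <- n_j + 1L
        a <- m$id[k]; b <- m$id[k + 1L]
        if (!(a %in% tc$id) || !(b %in% tc$id)) { bad <- bad + 1L; next }
        # effective genome direction of each member
        da <- if (m$orient[k] == torient[a]) "+" else "-"
        db <- if (m$orient[k + 1L] == torient[b]) "+" else "-"
        ok <- (idx[b] == idx[a] + 1L && da == "+" && db == "+") ||
              (idx[a] == idx[b] + 1L && da == "-" && db == "-")
        if (!ok) { bad <- bad + 1L; next }
        lo <- min(idx[a], idx[b]); hi <- max(idx[a], idx[b])
        if (tc$start[hi] > tc$end[lo]) {
          covered <- c(covered, IRanges::IRanges(start = tc$end[lo] + 1L,
                                                 end = tc$start[hi]))
        }
      }
    }
    rep$n_junctions <- n_j
    rep$misjoins <- bad
    rep$coverage <- sum(IRanges::width(IRanges::reduce(covered))) /
      truth$genome_len
  }
  if (!is.null(patches) && !is.null(paths) && !is.null(truth$contigs)) {
    errs <- patch_error_rates(paths, patches, truth)
    rep$patch_error_rate <- if (length(errs)) mean(errs) else NA_real_
    rep$n_patches_evaluated <- length(errs)
  }
  rep
}

# Per-patch error rate: global alignment of the patch against its true
# genome window (the inter-contig gap widened by the trims plus slack).
patch_error_rates <- function(paths, patches, truth, slack = 1500) {
  tc <- truth$contigs
  idx <- stats::setNames(seq_len(nrow(tc)), tc$id)
  errs <- numeric(0)
  for (ch in paths) {
    j <- ch$junctions
    if (nrow(j) == 0L) next
    for (k in seq_len(nrow(j))) {
      pid <- j$patch_id[k]
      if (is.na(pid) || is.null(patches[[pid]])) next
      p <- patches[[pid]]
      if (nchar(p$seq) == 0L) next
      a <- j$left_id[k]; b <- j$right_id[k]
      if (!(a %in% tc$id) || !(b %in% tc$id)) next
      lo <- min(idx[a], idx[b]); hi <- max(idx[a], idx[b])
      win_s <- max(0L, tc$end[lo] - slack)
      win_e <- min(truth$genome_len, tc$start[hi] + slack)
      if (win_e <= win_s) next
      win <- substr(truth$genome, win_s + 1L, win_e)
      best <- -Inf; bid <- NA_real_
      for (q in c(p$seq, revcomp(p$seq))) {
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), Biostrings::DNAString(win),
          type = "global-local", substitutionMatrix = consensus_submat(),
          gapOpening = 3, gapExtension = 1)
        if (Biostrings::score(al) > best) {
          best <- Biostrings::score(al)
          bid <- aln_identity(al)
        }
      }
      if (!is.na(bid)) errs <- c(errs, 1 - bid)
    }
  }
  errs
}
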