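# Scaffold emission: FASTA, AGP v2.1 and a TSV junction report.
#
# Internally everything is 0-based half-open; AGP's 1-based inclusive
# convention is produced here, at the boundary, only.

#' Compose and write scaffold sequences
#'
#' Each path becomes one FASTA record: the concatenation of its oriented
#' member contigs with, at each junction, either the anchored patch (the
#' flanking contigs trimmed by the patch's `left_trim`/`right_trim`) or an
#' unfilled gap emitted as a run of N of the estimated size clamped to
#' \[100, 1e6\]. The companion AGP v2.1 file describes the component layout
#' (`W` rows for contig and patch components, `N` rows for unfilled gaps)
#' and the junction report records one TSV row per junction.
#'
#' @param paths list of chains (ordered oriented members + junction rows).
#' @param patches named list of anchored patches keyed by the junction's
#'   `patch_id`; entries may be `NULL` (demoted junctions become N-gaps).
#' @param contigs named [Biostrings::DNAStringSet] with every member
#'   sequence.
#' @param out_fasta,out_agp,out_junctions output paths (`NULL` skips the
#'   corresponding file).
#' @param prefix scaffold name prefix.
#' @return invisibly, a list with `scaffolds` (DNAStringSet), `agp`
#'   (data.frame) and `junctions` (data.frame).
#' @export
write_scaffolds <- function(paths, patches, contigs, out_fasta = NULL,
                            out_agp = NULL, out_junctions = NULL,
                            prefix = "scaffold") {
  agp <- NULL
  jrep <- NULL
  seqs <- character(length(paths))
  snames <- sprintf("%s_%05d", prefix, seq_along(paths))
  patch_counter <- 0L
  patch_components <- list()
  for (p in seq_along(paths)) {
    ch <- paths[[p]]
    m <- ch$members
    jn <- ch$junctions
    if (any(!m$id %in% names(contigs)))
      stop("missing contig sequence: ",
           paste(setdiff(m$id, names(contigs)), collapse = ", "))
    # oriented member sequences and per-member leading/trailing trims
    lead <- rep(0L, nrow(m)); tail_ <- rep(0L, nrow(m))
    jinfo <- vector("list", nrow(jn))
    if (nrow(jn) > 0L) for (k in seq_len(nrow(jn))) {
      pid <- jn$patch_id[k]
      pp <- if (!is.na(pid)) patches[[pid]] else NULL
      if (!is.null(pp)) {
        # orient the patch with the traversal
        fwd <- pp$contig_a == jn$left_id[k] && pp$side_a == jn$left_side[k]
        jinfo[[k]] <- list(type = "patch",
                           seq = if (fwd) pp$seq else revcomp(pp$seq),
                           lt = if (fwd) pp$left_trim else pp$right_trim,
                           rt = if (fwd) pp$right_trim else pp$left_trim,
                           support = pp$support, pid = pid)
        tail_[k] <- jinfo[[k]]$lt
        lead[k + 1L] <- jinfo[[k]]$rt
      } else {
        jinfo[[k]] <- list(type = "gap",
                           gap = as.integer(clamp(round(jn$gap[k]),
                                                  100, 1e6)),
                           support = jn$support[k])
      }
    }
    pieces <- character(0)
    pos <- 0L  # current scaffold length
    part <- 0L
    for (i in seq_len(nrow(m))) {
      s <- as.character(contigs[[m$id[i]]])
      clen <- nchar(s)
      if (m$orient[i] == "-") s <- revcomp(s)
      keep_start <- 1L + lead[i]
      keep_end <- nchar(s) - tail_[i]
      if (keep_end < keep_start)
        stop("trims exceed contig length for ", m$id[i])
      s <- substr(s, keep_start, keep_end)
      pieces <- c(pieces, s)
      part <- part + 1L
      # component coordinates on the original (unoriented) contig
      if (m$orient[i] == "+") {
        cb <- keep_start; ce <- keep_end
      } else {
        cb <- clen - keep_end + 1L; ce <- clen - keep_start + 1L
      }
      agp <- rbind(agp, data.frame(
        object = snames[p], object_beg = pos + 1L,
        object_end = pos + nchar(s), part_number = part,
        component_type = "W", component_id = m$id[i],
        component_beg = cb, component_end = ce,
        orientation = m$orient[i], stringsAsFactors = FALSE))
      pos <- pos + nchar(s)
      if (i <= length(jinfo) && !is.null(jinfo[[i]])) {
        ji <- jinfo[[i]]
        if (ji$type == "patch") {
          if (nchar(ji$seq) > 0L) {
            patch_counter <- patch_counter + 1L
            pid_out <- sprintf("patch_%05d", patch_counter)
            patch_components[[pid_out]] <- ji$seq
            pieces <- c(pieces, ji$seq)
            part <- part + 1L
            agp <- rbind(agp, data.frame(
              object = snames[p], object_beg = pos + 1L,
              object_end = pos + nchar(ji$seq), part_number = part,
              component_type = "W", component_id = pid_out,
              component_beg = 1L, component_end = nchar(ji$seq),
              orientation = "+", stringsAsFactors = FALSE))
            pos <- pos + nchar(ji$seq)
          }
          plen_out <- nchar(ji$seq)
        } else {
          pieces <- c(pieces, strrep("N", ji$gap))
          part <- part + 1L
          agp <- rbind(agp, data.frame(
            object = snames[p], object_beg = pos + 1L,
            object_end = pos + ji$gap, part_number = part,
            component_type = "N", component_id = as.character(ji$gap),
            component_beg = NA_integer_, component_end = NA_integer_,
            orientation = "scaffold", stringsAsFactors = FALSE))
          pos <- pos + ji$gap
          plen_out <- NA_integer_
        }
        jrep <- rbind(jrep, data.frame(
          scaffold = snames[p], left_contig = m$id[i],
          right_contig = m$id[i + 1L],
          orientation = paste0(m$orient[i], "/", m$orient[i + 1L]),
          gap_estimate = jn$gap[i], patch_length = plen_out,
          support = ji$support, stringsAsFactors = FALSE))
      }
    }
    seqs[p] <- paste(pieces, collapse = "")
  }
  scaffolds <- Biostrings::DNAStringSet(seqs)
  names(scaffolds) <- snames
  if (!is.null(out_fasta)) write_fasta(scaffolds, out_fasta)
  if (!is.null(out_agp)) {
    con <- file(out_agp, "w")
    cat("##agp-version\t2.1\n", file = con)
    if (!is.null(agp)) {
      a <- agp
      gap_row <- a$component_type == "N"
      lines <- ifelse(gap_row,
        paste(a$object, a$object_beg, a$object_end, a$part_number, "N",
              a$component_id, "scaffold", "yes", "align_genus", sep = "\t"),
        paste(a$object, a$object_beg, a$object_end, a$part_number, "W",
              a$component_id, a$component_beg, a$component_end,
              a$orientation, sep = "\t"))
      writeLines(lines, con)
    }
    close(con)
  }
  if (!is.null(out_junctions)) {
    hdr <- paste("scaffold", "left_contig", "right_contig", "orientation",
                 "gap_estimate", "patch_length", "support", sep = "\t")
    if (is.null(jrep)) {
      writeLines(hdr, out_junctions)
    } else {
      utils::write.table(jrep, out_junctions, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  invisible(list(scaffolds = scaffolds, agp = agp, junctions = jrep,
                 patch_components = patch_components))
}
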