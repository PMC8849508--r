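# Ordered, oriented contig chains.
#
# A chain is the member list of a super-node (and, at the end of resolution,
# of a scaffold path): an ordered data.frame of oriented contigs plus one
# junction row between each consecutive pair. Junction endpoints are stored
# at contig-end granularity ("left_id"/"left_side" is the end of the left
# contig that faces the junction) so that super-node ends can always be
# mapped back to the underlying contig end.

new_chain <- function(id, length) {
  list(
    members = data.frame(id = id, orient = "+", length = length,
                         stringsAsFactors = FALSE),
    junctions = empty_junctions())
}

empty_junctions <- function() {
  data.frame(left_id = character(0), left_side = character(0),
             right_id = character(0), right_side = character(0),
             support = numeric(0), gap = numeric(0),
             patch_id = character(0), stringsAsFactors = FALSE)
}

chain_rev <- function(ch) {
  m <- ch$members[rev(seq_len(nrow(ch$members))), , drop = FALSE]
  m$orient <- ifelse(m$orient == "+", "-", "+")
  rownames(m) <- NULL
  j <- ch$junctions
  if (nrow(j) > 0L) {
    j <- j[rev(seq_len(nrow(j))), , drop = FALSE]
    j <- data.frame(left_id = j$right_id, left_side = j$right_side,
                    right_id = j$left_id, right_side = j$left_side,
                    support = j$support, gap = j$gap, patch_id = j$patch_id,
                    stringsAsFactors = FALSE)
  }
  list(members = m, junctions = j)
}

# Join two chains with a junction row (already in chain frame).
chain_concat <- function(ch1, ch2, junction) {
  list(members = rbind(ch1$members, ch2$members),
       junctions = rbind(ch1$junctions, junction, ch2$junctions))
}

# Contig end corresponding to one extremity of a chain.
# side "begin" is the outward end of the first member, "end" of the last.
chain_terminal_contig_end <- function(ch, side) {
  m <- ch$members
  if (side == "begin") {
    row <- m[1L, ]
    s <- if (row$orient == "+") "begin" else "end"
  } else {
    row <- m[nrow(m), ]
    s <- if (row$orient == "+") "end" else "begin"
  }
  list(id = row$id, side = s)
}

# Total chain span: member lengths plus non-negative junction gap estimates.
chain_length <- function(ch) {
  sum(ch$members$length) + sum(pmax(ch$junctions$gap, 0))
}

# Canonical printable form, orientation-insensitive: the lexicographically
# smaller of the forward and reverse renderings. Used for path-set equality.
chain_signature <- function(ch) {
  render <- function(c2) paste(paste0(c2$members$id, c2$members$orient),
                               collapse = ",")
  f <- render(ch)
  r <- render(chain_rev(ch))
  if (f <= r) f else r
}
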