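# Proper-alignment filtering and link extraction.
#
# A joining sequence (long read or external contig) supports a junction
# between two contig ends when it aligns "properly" to both contigs: the
# alignment is long (>= min_aln_len, default 5 kb) and wherever the read
# continues past the alignment toward a contig end, the unaligned stub of
# the contig is at most max_overhang (default 1 kb). Overhangs are allowed
# because contig ends frequently carry local mis-assemblies; bounding them
# keeps repeat-induced spurious joins out.

#' Keep only the best alignments of each query
#'
#' For each query, alignments are ranked by residue matches (ties broken by
#' longer block, then target id, then target start) and kept greedily: an
#' alignment is dropped when at least half of its query interval is covered
#' by an already-kept, higher-ranked alignment of the same query. This keeps
#' one winner per query region while preserving alignments to different
#' regions (e.g. the two contigs flanking a junction).
#'
#' @param paf alignment `data.frame` from [parse_paf()].
#' @return the retained subset, ranked per query.
#' @export
select_best <- function(paf) {
  if (nrow(paf) == 0L) return(paf)
  out <- lapply(split(seq_len(nrow(paf)), paf$query_id), function(idx) {
    d <- paf[idx, , drop = FALSE]
    d <- d[order(-d$matches, -d$block_len, d$target_id, d$target_start), ,
           drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(d))) {
      ov <- 0
      len_i <- d$query_end[i] - d$query_start[i]
      dominated <- FALSE
      for (k in kept) {
        ov <- min(d$query_end[i], d$query_end[k]) -
          max(d$query_start[i], d$query_start[k])
        if (ov >= 0.5 * len_i) { dominated <- TRUE; break }
      }
      if (!dominated) kept <- c(kept, i)
    }
    d[kept, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify alignments as proper
#'
#' For each alignment the two contig sides are examined. On a side, let
#' `read_ext` be the read sequence extending past the alignment toward that
#' contig end and `contig_dist` the unaligned contig stub. The side is
#' *touched* when `read_ext > contig_dist` (the read extends past the contig
#' end). An alignment is proper iff its block length is at least
#' `min_aln_len` and every touched side has `contig_dist <= max_overhang`.
#' Alignments touching no end are `internal` (links require end proximity);
#' too-short or over-hanging alignments are rejected with a reason code.
#'
#' @param paf alignment `data.frame` (typically after [select_best()]).
#' @param min_aln_len minimum alignment block length in bp (default 5000).
#' @param max_overhang maximum unaligned contig stub at a touched end in bp
#'   (default 1000).
#' @return `paf` with added columns `status` (`proper`, `too_short`,
#'   `overhang_exceeded`, `internal`), `overhang` (bp), `touch_begin`,
#'   `touch_end` and `end_touched` (`begin`/`end`/`both`/`none`).
#' @export
classify_proper <- function(paf, min_aln_len = 5000, max_overhang = 1000) {
  n <- nrow(paf)
  if (n == 0L) {
    paf$status <- character(0); paf$overhang <- numeric(0)
    paf$touch_begin <- logical(0); paf$touch_end <- logical(0)
    paf$end_touched <- character(0)
    return(paf)
  }
  plus <- paf$strand == "+"
  # read extension beyond the alignment toward the contig's begin/end side
  ext_begin <- ifelse(plus, paf$query_start, paf$query_len - paf$query_end)
  ext_end <- ifelse(plus, paf$query_len - paf$query_end, paf$query_start)
  dist_begin <- paf$target_start
  dist_end <- paf$target_len - paf$target_end
  touch_begin <- ext_begin > dist_begin
  touch_end <- ext_end > dist_end
  overhang <- pmax(ifelse(touch_begin, dist_begin, 0),
                   ifelse(touch_end, dist_end, 0))
  status <- rep("proper", n)
  status[!touch_begin & !touch_end] <- "internal"
  status[(touch_begin & dist_begin > max_overhang) |
         (touch_end & dist_end > max_overhang)] <- "overhang_exceeded"
  status[paf$block_len < min_aln_len] <- "too_short"
  paf$status <- status
  paf$overhang <- overhang
  paf$touch_begin <- touch_begin
  paf$touch_end <- touch_end
  paf$end_touched <- ifelse(touch_begin & touch_end, "both",
                            ifelse(touch_begin, "begin",
                                   ifelse(touch_end, "end", "none")))
  paf
}

#' Extract candidate links between contig ends
#'
#' Joins with proper alignments to at least two distinct contigs yield one
#' link per *adjacent* pair of proper alignments ordered along the read;
#' joins aligning properly to a single contig contribute nothing. For a
#' pair, the left alignment must touch its read-forward exit end and the
#' right alignment its entry end. The gap estimate is the read-coordinate
#' distance between the projections of the two facing contig ends (negative
#' when they overlap on the read).
#'
#' @param proper output of [classify_proper()]; only rows with
#'   `status == "proper"` are used.
#' @param anchor_bp flanking anchor retained on each side of the extracted
#'   junction interval for later patch re-alignment (default 200).
#' @return a `data.frame` of links: `join_id`, `contig_a`, `side_a`,
#'   `contig_b`, `side_b`, `orientation`, `gap`, `rstart`, `rend` (0-based
#'   half-open junction interval on the read, anchors included) and `order`
#'   (1 for adjacent pairs; 2 for skip-one pairs, which are used only as
#'   repeat flank-pairing evidence, never as graph edges).
#' @export
extract_links <- function(proper, anchor_bp = 200) {
  pr <- proper[proper$status == "proper", , drop = FALSE]
  links <- NULL
  pair_link <- function(a, b, ord) {
    if (a$target_id == b$target_id) return(NULL)
    a_plus <- a$strand == "+"; b_plus <- b$strand == "+"
    side_a <- if (a_plus) "end" else "begin"      # read-forward exit end
    side_b <- if (b_plus) "begin" else "end"      # read-forward entry end
    a_touch <- if (a_plus) a$touch_end else a$touch_begin
    b_touch <- if (b_plus) b$touch_begin else b$touch_end
    if (!a_touch || !b_touch) return(NULL)
    proj_a <- a$query_end +
      (if (a_plus) a$target_len - a$target_end else a$target_start)
    proj_b <- b$query_start -
      (if (b_plus) b$target_start else b$target_len - b$target_end)
    data.frame(
      join_id = a$query_id, query_len = a$query_len,
      contig_a = a$target_id, side_a = side_a,
      contig_b = b$target_id, side_b = side_b,
      orientation = if (a$strand == b$strand) "forward" else "reverse",
      gap = proj_b - proj_a,
      rstart = max(0, a$query_end - anchor_bp),
      rend = min(a$query_len, b$query_start + anchor_bp),
      order = ord, stringsAsFactors = FALSE)
  }
  if (nrow(pr) > 0L) {
    for (idx in split(seq_len(nrow(pr)), pr$query_id)) {
      d <- pr[idx, , drop = FALSE]
      if (length(unique(d$target_id)) < 2L) next
      d <- d[order(d$query_start, d$query_end, d$target_id), , drop = FALSE]
      for (i in seq_len(nrow(d) - 1L)) {
        links <- rbind(links, pair_link(d[i, ], d[i + 1L, ], 1L))
        if (i + 2L <= nrow(d))
          links <- rbind(links, pair_link(d[i, ], d[i + 2L, ], 2L))
      }
    }
  }
  if (is.null(links)) {
    links <- data.frame(join_id = character(0), query_len = numeric(0),
                        contig_a = character(0), side_a = character(0),
                        contig_b = character(0), side_b = character(0),
                        orientation = character(0), gap = numeric(0),
                        rstart = numeric(0), rend = numeric(0),
                        order = integer(0), stringsAsFactors = FALSE)
  }
  links
}

#' Bundle concordant links into supported edges
#'
#' Links are grouped by the (orientation-canonical) pair of contig ends
#' they join; groups below `min_support` are dropped. More than one
#' supporting read is required by default when the joining set is deep
#' read coverage (`min_support = 2`); a single link suffices when joining
#' with another assembly (`min_support = 1`). The bundle gap estimate is
#' the median of the member gap estimates, robust to one aberrant spanning
#' read.
#'
#' @param links `data.frame` from [extract_links()].
#' @param min_support minimum number of supporting joins (default 2).
#' @param order which link order to bundle (1 = adjacent-pair scaffold
#'   links, 2 = skip-one repeat-evidence links).
#' @return a `data.frame` of bundles with columns `bundle_id`, `contig_a`,
#'   `side_a`, `contig_b`, `side_b`, `support`, `gap` and a list-column
#'   `members` of per-read junction intervals (`join_id`, `rstart`, `rend`,
#'   `flipped`).
#' @export
bundle_links <- function(links, min_support = 2, order = 1L) {
  if (!is.null(links$order))
    links <- links[links$order == order, , drop = FALSE]
  empty <- data.frame(bundle_id = character(0), contig_a = character(0),
                      side_a = character(0), contig_b = character(0),
                      side_b = character(0), support = integer(0),
                      gap = numeric(0), stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(links) == 0L) return(empty)
  links <- links[links$contig_a != links$contig_b, , drop = FALSE]
  if (nrow(links) == 0L) return(empty)
  ka <- end_key(links$contig_a, links$side_a)
  kb <- end_key(links$contig_b, links$side_b)
  flip <- kb < ka
  c_a <- ifelse(flip, links$contig_b, links$contig_a)
  s_a <- ifelse(flip, links$side_b, links$side_a)
  c_b <- ifelse(flip, links$contig_a, links$contig_b)
  s_b <- ifelse(flip, links$side_a, links$side_b)
  key <- paste(end_key(c_a, s_a), end_key(c_b, s_b), sep = "~")
  groups <- split(seq_len(nrow(links)), key)
  rows <- NULL
  members <- list()
  for (k in sort(names(groups))) {
    idx <- groups[[k]]
    if (length(idx) < min_support) next
    mem <- data.frame(join_id = links$join_id[idx],
                      rstart = links$rstart[idx], rend = links$rend[idx],
                      flipped = flip[idx], gap = links$gap[idx],
                      stringsAsFactors = FALSE)
    mem <- mem[order(mem$join_id, mem$rstart), , drop = FALSE]
    rownames(mem) <- NULL
    i1 <- idx[1L]
    rows <- rbind(rows, data.frame(
      bundle_id = k, contig_a = c_a[i1], side_a = s_a[i1],
      contig_b = c_b[i1], side_b = s_b[i1],
      support = length(idx), gap = stats::median(links$gap[idx]),
      stringsAsFactors = FALSE))
    members[[length(members) + 1L]] <- mem
  }
  if (is.null(rows)) return(empty)
  rows$members <- members
  rownames(rows) <- NULL
  rows
}
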