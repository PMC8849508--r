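# Contig graph construction and resolution.
#
# The graph is side-typed and undirected: each node (a contig, or after
# collapsing a super-node holding an ordered oriented contig chain) has a
# "begin" and an "end" side, and each edge joins one side of one node to one
# side of another. Incoming/outgoing in the description of the method is
# relative to each node's arbitrary begin->end direction, so "two or more
# incoming and two or more outgoing edges" is stated here
# orientation-invariantly as ">= 2 edges on each side".
#
# Resolution proceeds: collapse linear stretches into super-nodes; pop
# bubbles iteratively, keeping the longest branch; temporarily remove repeat
# nodes (>= 2 edges on both sides), recording their edges; collapse again;
# delete all edges at any side that still carries >= 2 edges (one global
# scan over a frozen degree snapshot); the remaining components are simple
# paths; finally re-insert repeats into path junctions where their recorded
# edges pair with a direct flank-to-flank edge, duplicating their sequence
# per insertion.

#' Build a contig graph
#'
#' @param contigs named numeric vector of contig lengths, or a named
#'   [Biostrings::DNAStringSet].
#' @param edges `data.frame` with columns `node1`, `side1`, `node2`, `side2`
#'   and optionally `support`, `gap`, `patch_id`. Sides are `"begin"` or
#'   `"end"`.
#' @return an object of class `contig_graph`.
#' @export
build_graph <- function(contigs, edges = NULL) {
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- stats::setNames(as.numeric(Biostrings::width(contigs)),
                               names(contigs))
  }
  ids <- names(contigs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("contigs must have unique names")
  nodes <- lapply(seq_along(ids), function(i) new_chain(ids[i], contigs[[i]]))
  names(nodes) <- ids
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(node1 = character(0), side1 = character(0),
                        node2 = character(0), side2 = character(0),
                        support = numeric(0), gap = numeric(0),
                        patch_id = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$support)) edges$support <- 1
    if (is.null(edges$gap)) edges$gap <- 0
    if (is.null(edges$patch_id)) edges$patch_id <- NA_character_
    edges <- edges[, c("node1", "side1", "node2", "side2",
                       "support", "gap", "patch_id")]
    unknown <- setdiff(c(edges$node1, edges$node2), ids)
    if (length(unknown) > 0L)
      stop("edge names unknown contig(s): ", paste(unknown, collapse = ", "))
    if (any(!c(edges$side1, edges$side2) %in% c("begin", "end")))
      stop("edge sides must be 'begin' or 'end'")
    if (any(edges$node1 == edges$node2 & edges$side1 == edges$side2))
      stop("self-loop on the same node side is not allowed")
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, counter = 0L),
            class = "contig_graph")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat("contig_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# Degree of every node end, named by end key; zero entries included.
graph_degrees <- function(g) {
  keys <- c(end_key(names(g$nodes), "begin"), end_key(names(g$nodes), "end"))
  deg <- stats::setNames(integer(length(keys)), keys)
  if (nrow(g$edges) > 0L) {
    tab <- table(c(end_key(g$edges$node1, g$edges$side1),
                   end_key(g$edges$node2, g$edges$side2)))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

node_end_to_contig_end <- function(g, id, side) {
  chain_terminal_contig_end(g$nodes[[id]], side)
}

node_length <- function(g, id) chain_length(g$nodes[[id]])

# Members of a node as a character vector of contig ids.
node_members <- function(g, id) g$nodes[[id]]$members$id

#' Collapse linear stretches into super-nodes
#'
#' A node is *linear* when it has at most one edge on each side. Maximal
#' runs of linear nodes connected through their single-edge sides are
#' replaced by a super-node whose member chain preserves order and
#' orientation and whose length is the sum of member lengths plus
#' (non-negative) junction gap estimates. A node with two edges on one side
#' never joins a super-node, so branching structure is preserved for bubble
#' and repeat detection. Idempotent. All-linear cycles are opened at a
#' deterministic edge (largest edge key) and keep that edge as a
#' begin--end self-loop on the super-node.
#'
#' @param g a `contig_graph`.
#' @return the collapsed `contig_graph`.
#' @export
collapse_linear <- function(g) {
  deg <- graph_degrees(g)
  ids <- names(g$nodes)
  linear <- ids[deg[end_key(ids, "begin")] <= 1L &
                deg[end_key(ids, "end")] <= 1L]
  if (length(linear) < 2L || nrow(g$edges) == 0L) return(g)
  is_lin <- stats::setNames(ids %in% linear, ids)
  e <- g$edges
  mergeable <- which(e$node1 != e$node2 & is_lin[e$node1] & is_lin[e$node2])
  if (length(mergeable) == 0L) return(g)
  # each end of a linear node carries at most one edge
  edge_at <- new.env(parent = emptyenv())
  for (i in mergeable) {
    assign(end_key(e$node1[i], e$side1[i]), i, envir = edge_at)
    assign(end_key(e$node2[i], e$side2[i]), i, envir = edge_at)
  }
  get_edge <- function(id, side) {
    k <- end_key(id, side)
    if (exists(k, envir = edge_at, inherits = FALSE))
      get(k, envir = edge_at) else NA_integer_
  }
  edge_other <- function(i, id, side) {
    if (e$node1[i] == id && e$side1[i] == side)
      list(id = e$node2[i], side = e$side2[i])
    else list(id = e$node1[i], side = e$side1[i])
  }

  visited <- new.env(parent = emptyenv())
  new_nodes <- list()
  drop_nodes <- character(0)
  internal_edges <- integer(0)
  remap <- list()  # old end key -> c(new_id, new_side)
  counter <- g$counter

  for (seed_id in sort(intersect(linear, unique(c(e$node1[mergeable],
                                                  e$node2[mergeable]))))) {
    if (exists(seed_id, envir = visited, inherits = FALSE)) next
    # walk "left" to a terminus (or detect a cycle)
    cur <- seed_id; ex <- "begin"; seen <- seed_id; cycle <- FALSE
    repeat {
      i <- get_edge(cur, ex)
      if (is.na(i)) break
      nb <- edge_other(i, cur, ex)
      if (nb$id %in% seen) { cycle <- TRUE; break }
      seen <- c(seen, nb$id)
      cur <- nb$id; ex <- other_side(nb$side)
    }
    if (cycle) {
      start <- min(seen); start_ex <- "end"
    } else {
      start <- cur; start_ex <- other_side(ex)
    }
    # forward walk collecting members and junction payloads
    members <- start
    chain <- if (start_ex == "end") g$nodes[[start]]
             else chain_rev(g$nodes[[start]])
    cedges <- integer(0)
    cur <- start; ex <- start_ex
    last_ex <- ex
    repeat {
      i <- get_edge(cur, ex)
      if (is.na(i)) { last_ex <- ex; break }
      nb <- edge_other(i, cur, ex)
      if (nb$id == start) { last_ex <- ex; break }  # closing edge of a cycle
      le <- node_end_to_contig_end(g, cur, ex)
      re <- node_end_to_contig_end(g, nb$id, nb$side)
      jrow <- data.frame(left_id = le$id, left_side = le$side,
                         right_id = re$id, right_side = re$side,
                         support = e$support[i], gap = e$gap[i],
                         patch_id = e$patch_id[i], stringsAsFactors = FALSE)
      nxt_chain <- if (nb$side == "begin") g$nodes[[nb$id]]
                   else chain_rev(g$nodes[[nb$id]])
      chain <- chain_concat(chain, nxt_chain, jrow)
      cedges <- c(cedges, i)
      members <- c(members, nb$id)
      cur <- nb$id; ex <- other_side(nb$side)
    }
    if (length(members) < 2L) {
      assign(seed_id, TRUE, envir = visited)
      next
    }
    counter <- counter + 1L
    new_id <- sprintf("sn%06d", counter)
    rownames(chain$members) <- NULL; rownames(chain$junctions) <- NULL
    new_nodes[[new_id]] <- chain
    for (m in members) assign(m, TRUE, envir = visited)
    drop_nodes <- c(drop_nodes, members)
    internal_edges <- c(internal_edges, cedges)
    remap[[end_key(start, other_side(start_ex))]] <- c(new_id, "begin")
    remap[[end_key(cur, last_ex)]] <- c(new_id, "end")
  }
  if (length(new_nodes) == 0L) return(g)
  keep <- setdiff(names(g$nodes), drop_nodes)
  nodes <- c(g$nodes[keep], new_nodes)
  e2 <- if (length(internal_edges) > 0L)
    e[-internal_edges, , drop = FALSE] else e
  if (nrow(e2) > 0L) {
    for (j in seq_len(nrow(e2))) {
      k1 <- end_key(e2$node1[j], e2$side1[j])
      if (!is.null(remap[[k1]])) {
        e2$node1[j] <- remap[[k1]][1L]; e2$side1[j] <- remap[[k1]][2L]
      }
      k2 <- end_key(e2$node2[j], e2$side2[j])
      if (!is.null(remap[[k2]])) {
        e2$node2[j] <- remap[[k2]][1L]; e2$side2[j] <- remap[[k2]][2L]
      }
    }
  }
  rownames(e2) <- NULL
  structure(list(nodes = nodes, edges = e2, counter = counter),
            class = "contig_graph")
}

#' Pop bubbles iteratively
#'
#' A bubble is a set of two or more branch nodes (exactly one edge on each
#' side) whose edges all attach to the same pair of node ends: a common
#' source and a common sink. Bubbles typically arise from haplotype variants
#' assembled into separate contigs. Each bubble is popped by keeping the
#' branch of greatest total length (member lengths plus gap estimates; ties
#' broken by the lexicographically smallest member id) and deleting the
#' others, whose member contigs are reported as removed haplotype variants.
#' Popping alternates with [collapse_linear()] until a fixed point.
#'
#' @param g a `contig_graph` (collapsed or not; collapsing is re-run).
#' @return a list with elements `graph`, `haplotigs` (a `data.frame` of
#'   removed contig ids and the bubble they belonged to) and
#'   `dropped_patches` (patch ids of discarded junctions).
#' @export
pop_bubbles <- function(g) {
  haplotigs <- data.frame(contig = character(0), bubble = character(0),
                          stringsAsFactors = FALSE)
  dropped <- character(0)
  repeat {
    g <- collapse_linear(g)
    deg <- graph_degrees(g)
    ids <- names(g$nodes)
    cand <- ids[deg[end_key(ids, "begin")] == 1L &
                deg[end_key(ids, "end")] == 1L]
    if (length(cand) == 0L) break
    e <- g$edges
    # attachment ends of each candidate branch node
    att <- lapply(cand, function(id) {
      i_b <- which((e$node1 == id & e$side1 == "begin") |
                   (e$node2 == id & e$side2 == "begin"))
      i_e <- which((e$node1 == id & e$side1 == "end") |
                   (e$node2 == id & e$side2 == "end"))
      if (length(i_b) != 1L || length(i_e) != 1L) return(NULL)
      oth <- function(i) {
        if (e$node1[i] == id) end_key(e$node2[i], e$side2[i])
        else end_key(e$node1[i], e$side1[i])
      }
      a <- oth(i_b); b <- oth(i_e)
      na <- split_end_key(a)$id; nb <- split_end_key(b)$id
      if (na == id || nb == id || na == nb) return(NULL)
      list(id = id, key = paste(sort(c(a, b)), collapse = "~"))
    })
    att <- Filter(Negate(is.null), att)
    if (length(att) == 0L) break
    keys <- vapply(att, `[[`, "", "key")
    groups <- split(vapply(att, `[[`, "", "id"), keys)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) == 0L) break
    for (k in sort(names(groups))) {
      branches <- groups[[k]]
      lens <- vapply(branches, function(id) node_length(g, id), 0)
      minids <- vapply(branches, function(id) min(node_members(g, id)), "")
      ord <- order(-lens, minids)
      losers <- branches[ord[-1L]]
      for (id in losers) {
        ch <- g$nodes[[id]]
        haplotigs <- rbind(haplotigs,
                           data.frame(contig = ch$members$id, bubble = k,
                                      stringsAsFactors = FALSE))
        dropped <- c(dropped, ch$junctions$patch_id)
        ei <- which(g$edges$node1 == id | g$edges$node2 == id)
        dropped <- c(dropped, g$edges$patch_id[ei])
        g$edges <- g$edges[setdiff(seq_len(nrow(g$edges)), ei), , drop = FALSE]
        g$nodes[[id]] <- NULL
      }
      rownames(g$edges) <- NULL
    }
  }
  list(graph = g, haplotigs = haplotigs,
       dropped_patches = dropped[!is.na(dropped)])
}

#' Resolve repeats and remaining branches into linear paths
#'
#' Implements the final resolution of a bubble-free graph: (1) nodes with
#' two or more edges on *both* sides are repeats; they are removed and
#' their edges recorded at contig-end granularity; (2) linear stretches are
#' re-collapsed; (3) on a frozen degree snapshot, every node side still
#' carrying two or more edges has all its edges deleted (a side with exactly
#' one edge keeps it); (4) the remaining components are simple paths
#' (all-linear cycles are opened deterministically); (5) each repeat is
#' re-inserted into a path junction when its recorded edges pair the two
#' junction flanks on opposite repeat sides and a direct flank-to-flank
#' edge supports the traversal -- the repeat's sequence is duplicated once
#' per insertion, and repeats with no such pairing are emitted standalone.
#' Pairings are chosen greedily by maximum summed support, each junction
#' used at most once.
#'
#' Two kinds of flank-pairing evidence are accepted: an internal path
#' junction whose direct flank-to-flank edge survived resolution (the
#' typical case for hand-built graphs, where joining sequences spanning the
#' whole repeat contributed a direct edge), and -- when `evidence` is
#' supplied -- a pair of free path ends listed in the evidence table
#' (skip-one bundles from reads spanning the whole repeat contig; see
#' [extract_links()]), in which case the two paths are joined through the
#' repeat.
#'
#' @param g a bubble-free `contig_graph` (output of [pop_bubbles()]).
#' @param evidence optional `data.frame` of flank-pairing evidence with
#'   columns `contig_a`, `side_a`, `contig_b`, `side_b` (e.g. skip-one
#'   bundles from [bundle_links()] with `order = 2`).
#' @return a list with elements `paths` (list of chains), `repeat_info`
#'   (`data.frame` of repeat node ids, their member contigs and insertion
#'   counts) and `dropped_patches`.
#' @export
resolve_repeats_and_branches <- function(g, evidence = NULL) {
  dropped <- character(0)
  # self-edges (circularisations) cannot join two different contigs;
  # a begin--end self-loop on a super-node is an all-linear cycle and is
  # opened deterministically at its smallest member contig id
  tmp <- drop_self_loops(g)
  g <- tmp$graph; dropped <- c(dropped, tmp$dropped)
  deg <- graph_degrees(g)
  ids <- names(g$nodes)
  repeats <- sort(ids[deg[end_key(ids, "begin")] >= 2L &
                      deg[end_key(ids, "end")] >= 2L])
  # record repeat edges at contig-end granularity
  rec <- data.frame(rep_id = character(0), rep_side = character(0),
                    other_key = character(0), support = numeric(0),
                    gap = numeric(0), patch_id = character(0),
                    stringsAsFactors = FALSE)
  rep_chains <- g$nodes[repeats]
  if (length(repeats) > 0L) {
    e <- g$edges
    for (r in repeats) {
      idx <- which(e$node1 == r | e$node2 == r)
      for (i in idx) {
        ends <- list(list(id = e$node1[i], side = e$side1[i]),
                     list(id = e$node2[i], side = e$side2[i]))
        mine <- which(vapply(ends, function(x) x$id == r, TRUE))
        for (m in mine) {
          oth <- ends[[if (m == 1L) 2L else 1L]]
          if (oth$id %in% repeats) next  # repeat-repeat: out of scope
          ce <- node_end_to_contig_end(g, oth$id, oth$side)
          rec <- rbind(rec, data.frame(
            rep_id = r, rep_side = ends[[m]]$side,
            other_key = end_key(ce$id, ce$side),
            support = e$support[i], gap = e$gap[i],
            patch_id = e$patch_id[i], stringsAsFactors = FALSE))
        }
      }
    }
    drop_e <- which(e$node1 %in% repeats | e$node2 %in% repeats)
    g$edges <- e[setdiff(seq_len(nrow(e)), drop_e), , drop = FALSE]
    g$nodes[repeats] <- NULL
    rownames(g$edges) <- NULL
  }
  g <- collapse_linear(g)
  # branch breaking on a frozen degree snapshot
  deg <- graph_degrees(g)
  busy <- names(deg)[deg >= 2L]
  if (length(busy) > 0L && nrow(g$edges) > 0L) {
    k1 <- end_key(g$edges$node1, g$edges$side1)
    k2 <- end_key(g$edges$node2, g$edges$side2)
    del <- which(k1 %in% busy | k2 %in% busy)
    dropped <- c(dropped, g$edges$patch_id[del])
    g$edges <- g$edges[setdiff(seq_len(nrow(g$edges)), del), , drop = FALSE]
  }
  g <- collapse_linear(g)
  tmp <- drop_self_loops(g)
  g <- tmp$graph; dropped <- c(dropped, tmp$dropped)
  stopifnot(nrow(g$edges) == 0L)
  ord <- order(vapply(g$nodes, function(ch) min(ch$members$id), ""))
  paths <- unname(g$nodes[ord])

  # re-insert repeats where flank-pairing evidence exists
  jreg <- list()  # internal junction key -> list(path, idx)
  for (p in seq_along(paths)) {
    j <- paths[[p]]$junctions
    if (nrow(j) == 0L) next
    for (k in seq_len(nrow(j))) {
      key <- paste(sort(c(end_key(j$left_id[k], j$left_side[k]),
                          end_key(j$right_id[k], j$right_side[k]))),
                   collapse = "~")
      jreg[[key]] <- list(path = p, idx = k)
    }
  }
  ereg <- list()  # free path-end contig-end key -> list(path, which)
  for (p in seq_along(paths)) {
    hb <- chain_terminal_contig_end(paths[[p]], "begin")
    he <- chain_terminal_contig_end(paths[[p]], "end")
    ereg[[end_key(hb$id, hb$side)]] <- list(path = p, which = "begin")
    ereg[[end_key(he$id, he$side)]] <- list(path = p, which = "end")
  }
  ev_keys <- character(0)
  if (!is.null(evidence) && nrow(evidence) > 0L) {
    ev_keys <- paste(
      pmin(end_key(evidence$contig_a, evidence$side_a),
           end_key(evidence$contig_b, evidence$side_b)),
      pmax(end_key(evidence$contig_a, evidence$side_a),
           end_key(evidence$contig_b, evidence$side_b)), sep = "~")
  }
  cands <- NULL
  if (nrow(rec) > 0L) {
    rb <- rec[rec$rep_side == "begin", , drop = FALSE]
    re <- rec[rec$rep_side == "end", , drop = FALSE]
    for (r in unique(rec$rep_id)) {
      b_i <- which(rb$rep_id == r); e_i <- which(re$rep_id == r)
      tb <- chain_terminal_contig_end(rep_chains[[r]], "begin")
      te <- chain_terminal_contig_end(rep_chains[[r]], "end")
      tb_key <- end_key(tb$id, tb$side); te_key <- end_key(te$id, te$side)
      for (bi in b_i) for (ei in e_i) {
        X <- rb$other_key[bi]; Y <- re$other_key[ei]
        if (X == Y) next
        key <- paste(sort(c(X, Y)), collapse = "~")
        kind <- if (!is.null(jreg[[key]])) "junction"
                else if (key %in% ev_keys && !is.null(ereg[[X]]) &&
                         !is.null(ereg[[Y]])) "free"
                else next
        # direction-independent tie-break: the repeat terminal contig end
        # that pairs with the smaller flank key
        tkey <- if (X <= Y) tb_key else te_key
        cands <- rbind(cands, data.frame(
          rep_id = r, rep_min = min(rep_chains[[r]]$members$id),
          jkey = key, X = X, Y = Y, tkey = tkey, kind = kind,
          score = rb$support[bi] + re$support[ei],
          b_row = bi, e_row = ei, stringsAsFactors = FALSE))
      }
    }
  }
  insertions <- stats::setNames(integer(length(repeats)), repeats)
  todo <- list()       # internal-junction splices
  free_ins <- list()   # free-end joins
  if (!is.null(cands) && nrow(cands) > 0L) {
    cands <- cands[order(-cands$score, cands$rep_min, cands$jkey,
                         cands$tkey), , drop = FALSE]
    taken <- character(0)
    used_ends <- character(0)
    pcomp <- seq_along(paths)  # union-find: paths joined so far
    pfind <- function(x) { while (pcomp[x] != x) x <- pcomp[x]; x }
    for (i in seq_len(nrow(cands))) {
      key <- cands$jkey[i]
      eb <- rec[rec$rep_side == "begin", ][cands$b_row[i], ]
      ee <- rec[rec$rep_side == "end", ][cands$e_row[i], ]
      if (cands$kind[i] == "junction") {
        if (key %in% taken) next
        taken <- c(taken, key)
        loc <- jreg[[key]]
        todo[[length(todo) + 1L]] <- list(
          path = loc$path, idx = loc$idx, rep_id = cands$rep_id[i],
          eb = eb, ee = ee)
      } else {
        if (cands$X[i] %in% used_ends || cands$Y[i] %in% used_ends) next
        rx <- pfind(ereg[[cands$X[i]]]$path)
        ry <- pfind(ereg[[cands$Y[i]]]$path)
        if (rx == ry) next  # would close a cycle
        pcomp[rx] <- ry
        used_ends <- c(used_ends, cands$X[i], cands$Y[i])
        free_ins[[length(free_ins) + 1L]] <- list(
          X = cands$X[i], Y = cands$Y[i], rep_id = cands$rep_id[i],
          eb = eb, ee = ee)
      }
      insertions[cands$rep_id[i]] <- insertions[cands$rep_id[i]] + 1L
    }
  }
  if (length(todo) > 0L) {
    by_path <- split(todo, vapply(todo, `[[`, 0L, "path"))
    for (pn in names(by_path)) {
      p <- as.integer(pn)
      sp <- by_path[[pn]]
      sp <- sp[order(-vapply(sp, `[[`, 0L, "idx"))]
      for (s in sp) {
        j <- paths[[p]]$junctions[s$idx, ]
        L <- list(id = j$left_id, side = j$left_side)
        Lkey <- end_key(L$id, L$side)
        rch <- rep_chains[[s$rep_id]]
        if (s$eb$other_key == Lkey) {
          # enter the repeat via its begin side
          lpay <- s$eb; rpay <- s$ee
        } else {
          rch <- chain_rev(rch)
          lpay <- s$ee; rpay <- s$eb
        }
        rb_end <- chain_terminal_contig_end(rch, "begin")
        re_end <- chain_terminal_contig_end(rch, "end")
        row1 <- data.frame(left_id = j$left_id, left_side = j$left_side,
                           right_id = rb_end$id, right_side = rb_end$side,
                           support = lpay$support, gap = lpay$gap,
                           patch_id = lpay$patch_id, stringsAsFactors = FALSE)
        row2 <- data.frame(left_id = re_end$id, left_side = re_end$side,
                           right_id = j$right_id, right_side = j$right_side,
                           support = rpay$support, gap = rpay$gap,
                           patch_id = rpay$patch_id, stringsAsFactors = FALSE)
        dropped <- c(dropped, j$patch_id)
        m <- paths[[p]]$members
        jn <- paths[[p]]$junctions
        n <- nrow(m)
        paths[[p]] <- list(
          members = rbind(m[seq_len(s$idx), , drop = FALSE], rch$members,
                          m[seq(s$idx + 1L, n), , drop = FALSE]),
          junctions = rbind(
            jn[seq_len(s$idx - 1L), , drop = FALSE], row1, rch$junctions,
            row2,
            if (s$idx < nrow(jn)) jn[seq(s$idx + 1L, nrow(jn)), , drop = FALSE]
            else empty_junctions()))
        rownames(paths[[p]]$members) <- NULL
        rownames(paths[[p]]$junctions) <- NULL
      }
    }
  }
  # free-end insertions join two paths through the repeat
  if (length(free_ins) > 0L) {
    alias <- seq_along(paths)
    pal <- function(x) { while (alias[x] != x) x <- alias[x]; x }
    dead <- logical(length(paths))
    for (f in free_ins) {
      p1 <- pal(ereg[[f$X]]$path); p2 <- pal(ereg[[f$Y]]$path)
      ch1 <- paths[[p1]]; ch2 <- paths[[p2]]
      t1 <- chain_terminal_contig_end(ch1, "end")
      if (end_key(t1$id, t1$side) != f$X) ch1 <- chain_rev(ch1)
      t2 <- chain_terminal_contig_end(ch2, "begin")
      if (end_key(t2$id, t2$side) != f$Y) ch2 <- chain_rev(ch2)
      rch <- rep_chains[[f$rep_id]]  # begin side of the repeat faces X
      rb_end <- chain_terminal_contig_end(rch, "begin")
      re_end <- chain_terminal_contig_end(rch, "end")
      xs <- split_end_key(f$X); ys <- split_end_key(f$Y)
      row1 <- data.frame(left_id = xs$id, left_side = xs$side,
                         right_id = rb_end$id, right_side = rb_end$side,
                         support = f$eb$support, gap = f$eb$gap,
                         patch_id = f$eb$patch_id, stringsAsFactors = FALSE)
      row2 <- data.frame(left_id = re_end$id, left_side = re_end$side,
                         right_id = ys$id, right_side = ys$side,
                         support = f$ee$support, gap = f$ee$gap,
                         patch_id = f$ee$patch_id, stringsAsFactors = FALSE)
      merged <- chain_concat(chain_concat(ch1, rch, row1), ch2, row2)
      rownames(merged$members) <- NULL
      rownames(merged$junctions) <- NULL
      paths[[p1]] <- merged
      dead[p2] <- TRUE
      alias[p2] <- p1
    }
    paths <- paths[!dead]
  }
  # repeats never inserted become standalone paths
  for (r in repeats) {
    if (insertions[[r]] == 0L) {
      dropped <- c(dropped, rec$patch_id[rec$rep_id == r])
      paths[[length(paths) + 1L]] <- rep_chains[[r]]
    }
  }
  repeat_info <- data.frame(
    rep_id = repeats,
    members = vapply(repeats, function(r)
      paste(rep_chains[[r]]$members$id, collapse = ","), ""),
    insertions = as.integer(insertions),
    stringsAsFactors = FALSE)
  list(paths = paths, repeat_info = repeat_info,
       dropped_patches = unique(dropped[!is.na(dropped)]))
}

# Remove self-edges. A begin--end self-loop on a multi-member node closes
# an all-linear cycle: the member ring is opened so the path starts at the
# smallest member contig id in forward orientation, and the junction that
# precedes the new start is discarded (its patch is dropped).
drop_self_loops <- function(g) {
  dropped <- character(0)
  sl <- which(g$edges$node1 == g$edges$node2)
  for (i in sl) {
    id <- g$edges$node1[i]
    opened <- open_cycle(g$nodes[[id]], g$edges[i, ])
    g$nodes[[id]] <- opened$chain
    dropped <- c(dropped, opened$dropped)
  }
  if (length(sl) > 0L)
    g$edges <- g$edges[setdiff(seq_len(nrow(g$edges)), sl), , drop = FALSE]
  rownames(g$edges) <- NULL
  list(graph = g, dropped = dropped[!is.na(dropped)])
}

open_cycle <- function(ch, closing_edge) {
  n <- nrow(ch$members)
  if (n == 1L) return(list(chain = ch, dropped = closing_edge$patch_id))
  ce <- chain_terminal_contig_end(ch, "end")
  cb <- chain_terminal_contig_end(ch, "begin")
  closing <- data.frame(left_id = ce$id, left_side = ce$side,
                        right_id = cb$id, right_side = cb$side,
                        support = closing_edge$support,
                        gap = closing_edge$gap,
                        patch_id = closing_edge$patch_id,
                        stringsAsFactors = FALSE)
  m <- ch$members
  ring <- rbind(ch$junctions, closing)  # ring[k]: m[k] -> m[k %% n + 1]
  i <- which(m$id == min(m$id))[1L]
  if (m$orient[i] == "-") {
    m <- m[rev(seq_len(n)), , drop = FALSE]
    m$orient <- ifelse(m$orient == "+", "-", "+")
    perm <- c(rev(seq_len(n - 1L)), n)
    r <- ring[perm, , drop = FALSE]
    ring <- data.frame(left_id = r$right_id, left_side = r$right_side,
                       right_id = r$left_id, right_side = r$left_side,
                       support = r$support, gap = r$gap,
                       patch_id = r$patch_id, stringsAsFactors = FALSE)
    i <- which(m$id == min(m$id))[1L]
  }
  ord <- c(seq(i, n), if (i > 1L) seq_len(i - 1L))
  m <- m[ord, , drop = FALSE]
  ring <- ring[ord, , drop = FALSE]
  rownames(m) <- NULL; rownames(ring) <- NULL
  list(chain = list(members = m,
                    junctions = ring[seq_len(n - 1L), , drop = FALSE]),
       dropped = ring$patch_id[n])
}

#' Resolve a contig graph end to end
#'
#' Convenience wrapper running [collapse_linear()], [pop_bubbles()] and
#' [resolve_repeats_and_branches()].
#'
#' @param g a `contig_graph`.
#' @param evidence optional repeat flank-pairing evidence; see
#'   [resolve_repeats_and_branches()].
#' @return a list with `paths`, `haplotigs`, `repeat_info`,
#'   `dropped_patches`.
#' @export
resolve_graph <- function(g, evidence = NULL) {
  popped <- pop_bubbles(g)
  res <- resolve_repeats_and_branches(popped$graph, evidence = evidence)
  list(paths = res$paths, haplotigs = popped$haplotigs,
       repeat_info = res$repeat_info,
       dropped_patches = unique(c(popped$dropped_patches,
                                  res$dropped_patches)))
}

#' Read / write a graph as a tab-separated edge list
#'
#' The debug/fixture format has comment lines `#node <id> <length>` for the
#' nodes followed by tab-separated edge rows
#' `node_a side_a node_b side_b support gap`.
#'
#' @param path file path.
#' @return for `read_graph_tsv`, a `contig_graph`.
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  nl <- grep("^#node\\s", lines, value = TRUE)
  toks <- strsplit(sub("^#node\\s+", "", nl), "\\s+")
  lens <- stats::setNames(as.numeric(vapply(toks, `[[`, "", 2L)),
                          vapply(toks, `[[`, "", 1L))
  el <- lines[!grepl("^#", lines)]
  edges <- NULL
  if (length(el) > 0L) {
    f <- strsplit(el, "\t", fixed = TRUE)
    edges <- data.frame(
      node1 = vapply(f, `[[`, "", 1L), side1 = vapply(f, `[[`, "", 2L),
      node2 = vapply(f, `[[`, "", 3L), side2 = vapply(f, `[[`, "", 4L),
      support = as.numeric(vapply(f, `[[`, "", 5L)),
      gap = as.numeric(vapply(f, `[[`, "", 6L)),
      stringsAsFactors = FALSE)
  }
  build_graph(lens, edges)
}

#' @rdname read_graph_tsv
#' @param g a `contig_graph`.
#' @export
write_graph_tsv <- function(g, path) {
  hdr <- vapply(names(g$nodes), function(id)
    sprintf("#node %s %d", id, as.integer(node_length(g, id))), "")
  e <- g$edges
  rows <- if (nrow(e) > 0L)
    paste(e$node1, e$side1, e$node2, e$side2,
          format(e$support, trim = TRUE), format(e$gap, trim = TRUE),
          sep = "\t") else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
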