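# Independent brute-force oracles.
#
# oracle_resolve() re-implements the whole graph resolution (linear-chain
# merging, bubble popping, repeat removal, branch breaking, path
# extraction, repeat re-insertion) at contig level with naive full-scan
# data-frame passes, sharing no code with the package implementation.

oracle_select_best <- function(paf) {
  keep <- rep(TRUE, nrow(paf))
  rank_key <- function(i) {
    c(-paf$matches[i], -paf$block_len[i])
  }
  ord <- order(paf$query_id, -paf$matches, -paf$block_len, paf$target_id,
               paf$target_start)
  kept_by_query <- list()
  sel <- logical(nrow(paf))
  for (i in ord) {
    q <- paf$query_id[i]
    ok <- TRUE
    for (k in kept_by_query[[q]]) {
      ov <- min(paf$query_end[i], paf$query_end[k]) -
        max(paf$query_start[i], paf$query_start[k])
      if (ov >= 0.5 * (paf$query_end[i] - paf$query_start[i])) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      kept_by_query[[q]] <- c(kept_by_query[[q]], i)
      sel[i] <- TRUE
    }
  }
  paf[ord[sel[ord]], , drop = FALSE]
}

# ---- graph oracle ---------------------------------------------------------

o_deg <- function(E, id, side) {
  sum(E$a == id & E$sa == side) + sum(E$b == id & E$sb == side)
}

o_lin <- function(E, id) {
  o_deg(E, id, "begin") <= 1 && o_deg(E, id, "end") <= 1
}

o_flip_unit <- function(u) {
  u$members <- u$members[rev(seq_len(nrow(u$members))), , drop = FALSE]
  u$members$orient <- ifelse(u$members$orient == "+", "-", "+")
  u$gaps <- rev(u$gaps)
  rownames(u$members) <- NULL
  u
}

o_outer <- function(u, which) {
  m <- u$members
  if (which == "first") {
    side <- if (m$orient[1] == "+") "begin" else "end"
    paste0(m$id[1], "|", side)
  } else {
    side <- if (m$orient[nrow(m)] == "+") "end" else "begin"
    paste0(m$id[nrow(m)], "|", side)
  }
}

# Merge linear contigs into maximal chains by naive repeated passes.
o_units <- function(E, ids) {
  units <- lapply(ids, function(id) {
    list(members = data.frame(id = id, orient = "+",
                              stringsAsFactors = FALSE),
         gaps = numeric(0), internal = integer(0))
  })
  names(units) <- ids
  unit_of <- stats::setNames(ids, ids)
  lin <- stats::setNames(vapply(ids, function(id) o_lin(E, id), TRUE), ids)
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(E))) {
      a <- E$a[i]; b <- E$b[i]
      if (a == b) next
      if (!(a %in% names(unit_of)) || !(b %in% names(unit_of))) next
      if (!lin[[a]] || !lin[[b]]) next
      ua <- unit_of[[a]]; ub <- unit_of[[b]]
      if (ua == ub) next
      A <- units[[ua]]; B <- units[[ub]]
      # orient A so that a is its last member with side sa outward
      last_id <- A$members$id[nrow(A$members)]
      if (last_id != a || o_outer(A, "last") != paste0(a, "|", E$sa[i]))
        A <- o_flip_unit(A)
      stopifnot(o_outer(A, "last") == paste0(a, "|", E$sa[i]))
      first_id <- B$members$id[1]
      if (first_id != b || o_outer(B, "first") != paste0(b, "|", E$sb[i]))
        B <- o_flip_unit(B)
      stopifnot(o_outer(B, "first") == paste0(b, "|", E$sb[i]))
      A$members <- rbind(A$members, B$members)
      A$gaps <- c(A$gaps, E$gap[i], B$gaps)
      A$internal <- c(A$internal, i, B$internal)
      units[[ua]] <- A
      units[[ub]] <- NULL
      for (mid in A$members$id) unit_of[[mid]] <- ua
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  units
}

o_unit_len <- function(u, L) sum(L[u$members$id]) + sum(pmax(u$gaps, 0))

o_other_end <- function(E, i, key) {
  k1 <- paste0(E$a[i], "|", E$sa[i]); k2 <- paste0(E$b[i], "|", E$sb[i])
  if (k1 == key) k2 else k1
}

o_edges_at <- function(E, key) {
  which(paste0(E$a, "|", E$sa) == key | paste0(E$b, "|", E$sb) == key)
}

# Drop edges both of whose endpoints lie in the same unit (cycle-closing
# edges and single-contig self loops); report the member contigs of the
# cyclic units.
o_drop_intra <- function(E, units) {
  cyc <- character(0)
  drop <- integer(0)
  for (i in seq_len(nrow(E))) {
    for (un in names(units)) {
      ms <- units[[un]]$members$id
      if (E$a[i] %in% ms && E$b[i] %in% ms && !(i %in% units[[un]]$internal)) {
        drop <- c(drop, i)
        # single-contig self-loops just vanish; only true multi-member
        # cycles need the deterministic rotation
        if (length(ms) > 1) cyc <- c(cyc, ms)
      }
    }
  }
  list(E = if (length(drop)) E[-drop, , drop = FALSE] else E,
       cyclic = unique(cyc))
}

o_rotate_cycle <- function(u) {
  m <- u$members
  i <- which(m$id == min(m$id))[1]
  if (m$orient[i] == "-") {
    u <- o_flip_unit(u)
    m <- u$members
    i <- which(m$id == min(m$id))[1]
  }
  n <- nrow(m)
  ord <- c(seq(i, n), if (i > 1) seq_len(i - 1))
  u$members <- m[ord, , drop = FALSE]
  rownames(u$members) <- NULL
  u
}

oracle_resolve <- function(g) {
  ids <- names(g$nodes)
  L <- stats::setNames(vapply(ids, function(id)
    gapstitch:::node_length(g, id), 0), ids)
  E <- data.frame(a = g$edges$node1, sa = g$edges$side1,
                  b = g$edges$node2, sb = g$edges$side2,
                  support = g$edges$support, gap = g$edges$gap,
                  stringsAsFactors = FALSE)
  haplotigs <- character(0)
  alive <- ids

  # ---- bubble popping ----
  repeat {
    units <- o_units(E, alive)
    popped <- FALSE
    cand <- list()
    for (un in names(units)) {
      ob <- o_outer(units[[un]], "first")
      oe <- o_outer(units[[un]], "last")
      sb <- gapstitch:::split_end_key(ob); se <- gapstitch:::split_end_key(oe)
      if (o_deg(E, sb$id, sb$side) != 1 || o_deg(E, se$id, se$side) != 1)
        next
      eb <- o_edges_at(E, ob); ee <- o_edges_at(E, oe)
      if (length(eb) != 1 || length(ee) != 1) next
      a1 <- o_other_end(E, eb, ob); a2 <- o_other_end(E, ee, oe)
      n1 <- gapstitch:::split_end_key(a1)$id
      n2 <- gapstitch:::split_end_key(a2)$id
      ms <- units[[un]]$members$id
      if (n1 %in% ms || n2 %in% ms) next
      # attachments must be on two different units
      u1 <- names(units)[vapply(units, function(x) n1 %in% x$members$id, TRUE)]
      u2 <- names(units)[vapply(units, function(x) n2 %in% x$members$id, TRUE)]
      if (identical(u1, u2)) next
      cand[[un]] <- paste(sort(c(a1, a2)), collapse = "~")
    }
    if (length(cand) > 0) {
      groups <- split(names(cand), unlist(cand))
      groups <- groups[lengths(groups) >= 2]
      for (k in sort(names(groups))) {
        br <- groups[[k]]
        lens <- vapply(br, function(un) o_unit_len(units[[un]], L), 0)
        mins <- vapply(br, function(un) min(units[[un]]$members$id), "")
        losers <- br[order(-lens, mins)][-1]
        for (un in losers) {
          ms <- units[[un]]$members$id
          haplotigs <- c(haplotigs, ms)
          alive <- setdiff(alive, ms)
          E <- E[!(E$a %in% ms | E$b %in% ms), , drop = FALSE]
        }
        popped <- TRUE
      }
    }
    if (!popped) break
  }

  # ---- cycles present at entry to resolution ----
  units <- o_units(E, alive)
  di <- o_drop_intra(E, units)
  E <- di$E
  cyclic <- di$cyclic

  # ---- repeat removal ----
  units <- o_units(E, alive)
  recs <- list()
  rep_units <- list()
  for (un in names(units)) {
    ob <- o_outer(units[[un]], "first"); oe <- o_outer(units[[un]], "last")
    sb <- gapstitch:::split_end_key(ob); se <- gapstitch:::split_end_key(oe)
    if (o_deg(E, sb$id, sb$side) >= 2 && o_deg(E, se$id, se$side) >= 2) {
      r1 <- lapply(o_edges_at(E, ob), function(i)
        list(other = o_other_end(E, i, ob), support = E$support[i]))
      r2 <- lapply(o_edges_at(E, oe), function(i)
        list(other = o_other_end(E, i, oe), support = E$support[i]))
      recs[[un]] <- list(t1 = ob, t2 = oe, at_t1 = r1, at_t2 = r2)
      rep_units[[un]] <- units[[un]]
    }
  }
  for (un in names(rep_units)) {
    ms <- rep_units[[un]]$members$id
    alive <- setdiff(alive, ms)
    E <- E[!(E$a %in% ms | E$b %in% ms), , drop = FALSE]
  }

  # ---- branch breaking on a frozen degree snapshot ----
  if (nrow(E) > 0) {
    keys <- unique(c(paste0(E$a, "|", E$sa), paste0(E$b, "|", E$sb)))
    busy <- keys[vapply(keys, function(k) {
      s <- gapstitch:::split_end_key(k); o_deg(E, s$id, s$side) >= 2
    }, TRUE)]
    del <- paste0(E$a, "|", E$sa) %in% busy | paste0(E$b, "|", E$sb) %in% busy
    E <- E[!del, , drop = FALSE]
  }

  # ---- final paths ----
  units <- o_units(E, alive)
  di <- o_drop_intra(E, units)
  E <- di$E
  cyclic <- c(cyclic, di$cyclic)
  units <- o_units(E, alive)
  paths <- list()
  for (un in names(units)) {
    u <- units[[un]]
    if (any(u$members$id %in% cyclic)) u <- o_rotate_cycle(u)
    paths[[length(paths) + 1]] <- u
  }

  # ---- repeat re-insertion ----
  jreg <- list()
  for (p in seq_along(paths)) {
    m <- paths[[p]]$members
    if (nrow(m) < 2) next
    for (k in seq_len(nrow(m) - 1)) {
      lkey <- paste0(m$id[k], "|", if (m$orient[k] == "+") "end" else "begin")
      rkey <- paste0(m$id[k + 1], "|",
                     if (m$orient[k + 1] == "+") "begin" else "end")
      jreg[[paste(sort(c(lkey, rkey)), collapse = "~")]] <-
        list(path = p, idx = k, lkey = lkey, rkey = rkey)
    }
  }
  cands <- NULL
  for (un in names(recs)) {
    rc <- recs[[un]]
    for (e1 in rc$at_t1) for (e2 in rc$at_t2) {
      X <- e1$other; Y <- e2$other
      if (X == Y) next
      jkey <- paste(sort(c(X, Y)), collapse = "~")
      if (is.null(jreg[[jkey]])) next
      cands <- rbind(cands, data.frame(
        un = un, rep_min = min(rep_units[[un]]$members$id),
        jkey = jkey, X = X, Y = Y,
        tkey = if (X <= Y) rc$t1 else rc$t2,
        score = e1$support + e2$support, stringsAsFactors = FALSE))
    }
  }
  inserted <- stats::setNames(rep(FALSE, length(rep_units)),
                              names(rep_units))
  if (!is.null(cands)) {
    cands <- cands[order(-cands$score, cands$rep_min, cands$jkey,
                         cands$tkey), , drop = FALSE]
    taken <- character(0)
    splices <- list()
    for (i in seq_len(nrow(cands))) {
      if (cands$jkey[i] %in% taken) next
      taken <- c(taken, cands$jkey[i])
      loc <- jreg[[cands$jkey[i]]]
      ru <- rep_units[[cands$un[i]]]
      # orient the repeat so its t1 terminal faces the junction's left key
      # iff X (attached at t1) is the left flank
      if (cands$X[i] == loc$lkey) rm <- ru$members
      else rm <- o_flip_unit(ru)$members
      splices[[length(splices) + 1]] <- list(path = loc$path, idx = loc$idx,
                                             members = rm)
      inserted[cands$un[i]] <- TRUE
    }
    byp <- split(splices, vapply(splices, `[[`, 0L, "path"))
    for (pn in names(byp)) {
      p <- as.integer(pn)
      sp <- byp[[pn]]
      sp <- sp[order(-vapply(sp, `[[`, 0L, "idx"))]
      for (s in sp) {
        m <- paths[[p]]$members
        paths[[p]]$members <- rbind(m[seq_len(s$idx), , drop = FALSE],
                                    s$members,
                                    m[seq(s$idx + 1, nrow(m)), , drop = FALSE])
        rownames(paths[[p]]$members) <- NULL
      }
    }
  }
  for (un in names(rep_units)) {
    if (!inserted[[un]])
      paths[[length(paths) + 1]] <- rep_units[[un]]
  }
  chains <- lapply(paths, function(u)
    list(members = u$members, junctions = gapstitch:::empty_junctions()))
  list(paths = chains, haplotigs = sort(haplotigs))
}
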