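# graph_resolve: construction, collapsing, bubble popping, repeat and
# branch resolution.

simple_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(node1 = r[[1]], side1 = r[[2]], node2 = r[[3]],
               side2 = r[[4]],
               support = if (length(r) >= 5) as.numeric(r[[5]]) else 1,
               gap = if (length(r) >= 6) as.numeric(r[[6]]) else 100,
               stringsAsFactors = FALSE)))
}

test_that("build_graph validates inputs and keeps isolated nodes", {
  lens <- c(a = 1000, b = 2000, c = 3000)
  g <- build_graph(lens)
  expect_equal(length(g$nodes), 3L)
  expect_equal(nrow(g$edges), 0L)

  g <- build_graph(lens, simple_edges(list("a", "end", "b", "begin"),
                                      list("b", "end", "c", "begin")))
  expect_equal(nrow(g$edges), 2L)

  expect_error(build_graph(lens, simple_edges(list("a", "end", "z", "begin"))),
               "unknown contig")
  expect_error(build_graph(lens, simple_edges(list("a", "end", "a", "end"))),
               "self-loop")
  expect_equal(length(fig3_graph()$nodes), 12L)
})

test_that("collapse_linear merges linear runs and is idempotent", {
  lens <- c(c1 = 1000, c2 = 2000, c3 = 3000)
  g <- build_graph(lens, simple_edges(list("c1", "end", "c2", "begin"),
                                      list("c2", "end", "c3", "begin")))
  g2 <- collapse_linear(g)
  expect_equal(length(g2$nodes), 1L)
  ch <- g2$nodes[[1L]]
  expect_equal(ch$members$id, c("c1", "c2", "c3"))
  expect_equal(ch$members$orient, c("+", "+", "+"))
  expect_equal(nrow(g2$edges), 0L)
  g3 <- collapse_linear(g2)
  expect_equal(length(g3$nodes), 1L)

  # star graph: no linear interior, unchanged
  lens <- c(hub = 5000, l1 = 1000, l2 = 1000, l3 = 1000)
  star <- build_graph(lens, simple_edges(
    list("hub", "end", "l1", "begin"), list("hub", "end", "l2", "begin"),
    list("hub", "end", "l3", "begin")))
  s2 <- collapse_linear(star)
  expect_equal(length(s2$nodes), 4L)
  expect_equal(nrow(s2$edges), 3L)
})

test_that("collapse_linear respects branching nodes (Fig 3 layout)", {
  g <- collapse_linear(fig3_graph())
  # C1-C2 must NOT merge: C2 has two bubble edges on its end side
  ids <- names(g$nodes)
  expect_true("C1" %in% ids && "C2" %in% ids)
  # B1-B3 collapse into one super-node
  sn <- setdiff(ids, c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8",
                       "B2", "R"))
  expect_equal(length(sn), 1L)
  expect_equal(g$nodes[[sn]]$members$id, c("B1", "B3"))
})

test_that("pop_bubbles keeps the longest branch and reaches a fixed
           point on nested bubbles", {
  pb <- pop_bubbles(fig3_graph())
  expect_equal(pb$haplotigs$contig, "B2")

  # equal-length branches: winner is the lexicographically smallest id
  lens <- c(s = 5000, t = 5000, bX = 3000, bY = 3000)
  g <- build_graph(lens, simple_edges(
    list("s", "end", "bX", "begin"), list("s", "end", "bY", "begin"),
    list("bX", "end", "t", "begin"), list("bY", "end", "t", "begin")))
  pb <- pop_bubbles(g)
  expect_equal(pb$haplotigs$contig, "bY")

  # nested bubble: inner {p,q} inside one branch of outer {a-chain, x}
  lens <- c(s = 5000, t = 5000, a = 2000, b = 2000, p = 1500, q = 900,
            x = 1000)
  g <- build_graph(lens, simple_edges(
    list("s", "end", "a", "begin"), list("a", "end", "p", "begin"),
    list("a", "end", "q", "begin"), list("p", "end", "b", "begin"),
    list("q", "end", "b", "begin"), list("b", "end", "t", "begin"),
    list("s", "end", "x", "begin"), list("x", "end", "t", "begin")))
  pb <- pop_bubbles(g)
  expect_setequal(pb$haplotigs$contig, c("q", "x"))
  # fixed point: exhaustive scan finds no remaining bubble
  deg <- gapstitch:::graph_degrees(pb$graph)
  ids <- names(pb$graph$nodes)
  branch <- ids[deg[gapstitch:::end_key(ids, "begin")] == 1 &
                deg[gapstitch:::end_key(ids, "end")] == 1]
  expect_true(length(branch) <= 1L)  # a single chain remains, no parallels
  res <- resolve_repeats_and_branches(pb$graph)
  expect_equal(length(res$paths), 1L)
  expect_equal(res$paths[[1L]]$members$id, c("s", "a", "p", "b", "t"))
})

test_that("branch breaking deletes all edges on a >= 2-edge side and
           keeps single-edge sides", {
  # v has one edge on begin (kept) and two on end (both deleted)
  lens <- c(u = 4000, v = 4000, w1 = 3000, w2 = 3000)
  g <- build_graph(lens, simple_edges(
    list("u", "end", "v", "begin"), list("v", "end", "w1", "begin"),
    list("v", "end", "w2", "begin")))
  res <- resolve_repeats_and_branches(g)
  sigs <- path_signatures(res$paths)
  expect_true(any(grepl("u\\+,v\\+|v-,u-", sigs)))
  expect_equal(length(res$paths), 3L)  # u-v, w1, w2
})

test_that("Fig 3 resolves into the documented three paths with R
           duplicated; without C5-C8, C5 and C8 are standalone", {
  res <- resolve_graph(fig3_graph())
  expect_setequal(path_signatures(res$paths),
                  c("C1+,C2+,B1+,B3+,C3+,C4+", "C5+,R+,C8+", "C6+,R+,C7+"))
  expect_equal(res$repeat_info$insertions, 2L)
  expect_equal(res$haplotigs$contig, "B2")

  g <- fig3_graph()
  g$edges <- g$edges[!(g$edges$node1 == "C5" & g$edges$node2 == "C8"), ]
  res <- resolve_graph(g)
  expect_setequal(path_signatures(res$paths),
                  c("C1+,C2+,B1+,B3+,C3+,C4+", "C5+", "C6+,R+,C7+", "C8+"))
})

test_that("graph TSV round-trips nodes and edges", {
  g <- fig3_graph()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, tsv)
  g2 <- read_graph_tsv(tsv)
  expect_setequal(names(g2$nodes), names(g$nodes))
  expect_equal(nrow(g2$edges), nrow(g$edges))
  expect_identical(path_signatures(resolve_graph(g2)$paths),
                   path_signatures(resolve_graph(g)$paths))
})

test_that("resolution conserves contig ids (scaffolds + haplotigs,
           repeats >= once)", {
  for (seed in 1:40) {
    g <- rand_graph(seed)
    res <- resolve_graph(g)
    in_paths <- unlist(lapply(res$paths, function(ch) ch$members$id))
    hap <- unique(res$haplotigs$contig)
    reps <- unlist(strsplit(res$repeat_info$members, ","))
    expect_setequal(c(unique(in_paths), hap), names(g$nodes))
    expect_equal(length(intersect(in_paths, hap)), 0L)
    # non-repeat contigs appear exactly once
    non_rep <- setdiff(in_paths, reps)
    expect_true(all(table(in_paths[in_paths %in% non_rep]) == 1L),
                info = paste("seed", seed))
  }
})

test_that("pop_bubbles and collapse_linear are idempotent at their
           fixed points and never grow the graph", {
  for (seed in c(3, 14, 27, 31)) {
    g <- rand_graph(seed)
    n0 <- length(g$nodes); e0 <- nrow(g$edges)
    c1 <- collapse_linear(g)
    expect_lte(length(c1$nodes), n0)
    expect_lte(nrow(c1$edges), e0)
    c2 <- collapse_linear(c1)
    expect_equal(length(c2$nodes), length(c1$nodes))
    p1 <- pop_bubbles(c1)
    p2 <- pop_bubbles(p1$graph)
    expect_equal(length(p2$graph$nodes), length(p1$graph$nodes))
    expect_equal(nrow(p2$haplotigs), 0L)
  }
})

test_that("free path ends are joined through a repeat only with
           spanning evidence", {
  # collapsed repeat R between (u1,u2) and (u2,u3): no direct flank edges
  lens <- c(u1 = 9000, u2 = 9000, u3 = 9000, R = 6000)
  g <- build_graph(lens, simple_edges(
    list("u1", "end", "R", "begin", 5, 300),
    list("R", "end", "u2", "begin", 5, 310),
    list("u2", "end", "R", "begin", 4, 320),
    list("R", "end", "u3", "begin", 4, 330)))
  # without evidence: repeat cannot be placed, flanks stay standalone
  res <- resolve_graph(g)
  expect_setequal(path_signatures(res$paths), c("R+", "u1+", "u2+", "u3+"))
  # with spanning-read evidence for both pairings: u1-R-u2-R-u3
  ev <- data.frame(contig_a = c("u1", "u2"), side_a = c("end", "end"),
                   contig_b = c("u2", "u3"), side_b = c("begin", "begin"),
                   stringsAsFactors = FALSE)
  res <- resolve_graph(g, evidence = ev)
  expect_equal(path_signatures(res$paths), "u1+,R+,u2+,R+,u3+")
  expect_equal(res$repeat_info$insertions, 2L)
})
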