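# proper_alignments: best-alignment selection, proper classification,
# link extraction, bundling.

test_that("select_best keeps dominant alignments and disjoint intervals", {
  # two overlapping alignments of r1 to c1: only the higher-matches one kept
  paf <- rbind(paf_row(matches = 5800, block_len = 6000),
               paf_row(matches = 4000, block_len = 6000,
                       target_start = 43000, target_end = 49000))
  kept <- select_best(paf)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$matches, 5800)

  # disjoint query intervals to two contigs: both kept
  paf <- rbind(paf_row(query_start = 0, query_end = 4000, target_id = "c1"),
               paf_row(query_start = 5000, query_end = 9000,
                       target_id = "c2"))
  expect_equal(nrow(select_best(paf)), 2L)
})

test_that("select_best matches the brute-force dominance filter", {
  sig <- function(d) sort(paste(d$query_id, d$target_id, d$query_start,
                                d$query_end, d$matches))
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:40, 1)
    qlen <- 20000
    qs <- sample(0:(qlen - 2000), n, TRUE)
    span <- sample(500:8000, n, TRUE)
    qe <- pmin(qlen, qs + span)
    paf <- data.frame(
      query_id = sample(sprintf("r%d", 1:3), n, TRUE), query_len = qlen,
      query_start = qs, query_end = qe,
      strand = sample(c("+", "-"), n, TRUE),
      target_id = sample(sprintf("c%d", 1:4), n, TRUE),
      target_len = 50000, target_start = 0, target_end = qe - qs,
      matches = sample(100:8000, n, TRUE), block_len = qe - qs,
      mapq = 60, stringsAsFactors = FALSE)
    expect_identical(sig(select_best(paf)), sig(oracle_select_best(paf)),
                     info = paste("seed", seed))
  }
})

test_that("classify_proper applies the 5 kb / 1 kb thresholds", {
  # proper: 6 kb block, read extends past contig end, 500 bp overhang
  a <- classify_proper(paf_row(query_len = 10000, query_start = 0,
                               query_end = 6000, target_start = 43500,
                               target_end = 49500, target_len = 50000,
                               block_len = 6000))
  expect_equal(a$status, "proper")
  expect_equal(a$overhang, 500)
  expect_equal(a$end_touched, "end")

  # shorter than 5 kb: rejected
  a <- classify_proper(paf_row(block_len = 4999))
  expect_equal(a$status, "too_short")

  # 1.5 kb overhang while the read continues: rejected
  a <- classify_proper(paf_row(query_len = 20000, query_start = 0,
                               query_end = 8000, target_start = 40500,
                               target_end = 48500, target_len = 50000,
                               matches = 7800, block_len = 8000))
  expect_equal(a$status, "overhang_exceeded")

  # wholly interior alignment, read terminates before either end: internal
  a <- classify_proper(paf_row(query_len = 7000, query_start = 100,
                               query_end = 6900, target_start = 20000,
                               target_end = 26800, target_len = 50000,
                               matches = 6500, block_len = 6800))
  expect_equal(a$status, "internal")
})

test_that("classify_proper agrees with a geometric embedding oracle", {
  # oracle: embed the read in contig coordinates and compare interval ends
  oracle <- function(r, min_len, max_ov) {
    if (r$strand == "+") {
      rs <- r$target_start - r$query_start
      re <- r$target_end + (r$query_len - r$query_end)
    } else {
      rs <- r$target_start - (r$query_len - r$query_end)
      re <- r$target_end + r$query_start
    }
    tb <- rs < 0
    te <- re > r$target_len
    db <- r$target_start
    de <- r$target_len - r$target_end
    if (r$block_len < min_len) return("too_short")
    if ((tb && db > max_ov) || (te && de > max_ov))
      return("overhang_exceeded")
    if (!tb && !te) return("internal")
    "proper"
  }
  set.seed(11)
  for (i in 1:400) {
    tlen <- sample(2000:30000, 1)
    ts <- sample(0:(tlen - 500), 1)
    te <- ts + sample(400:(tlen - ts), 1)
    qlen <- sample((te - ts):40000, 1)
    qs <- sample(0:(qlen - (te - ts)), 1)
    qe <- qs + (te - ts)
    r <- paf_row(query_len = qlen, query_start = qs, query_end = qe,
                 strand = sample(c("+", "-"), 1), target_len = tlen,
                 target_start = ts, target_end = te,
                 matches = te - ts, block_len = te - ts)
    got <- classify_proper(r, min_aln_len = 3000, max_overhang = 800)
    expect_equal(got$status, oracle(r, 3000, 800),
                 info = paste("case", i))
  }
})

make_spanning_paf <- function() {
  # read r1 spans c1 (end) then c2 (begin) with 700 bp between projections
  rbind(
    paf_row(query_id = "r1", query_len = 14000, query_start = 0,
            query_end = 6000, strand = "+", target_id = "c1",
            target_len = 30000, target_start = 24000, target_end = 30000,
            matches = 5900, block_len = 6000),
    paf_row(query_id = "r1", query_len = 14000, query_start = 6700,
            query_end = 13500, strand = "+", target_id = "c2",
            target_len = 40000, target_start = 0, target_end = 6800,
            matches = 6700, block_len = 6800))
}

test_that("extract_links builds junctions from adjacent proper pairs", {
  cls <- classify_proper(make_spanning_paf())
  links <- extract_links(cls)
  l1 <- links[links$order == 1L, ]
  expect_equal(nrow(l1), 1L)
  expect_equal(l1$contig_a, "c1"); expect_equal(l1$side_a, "end")
  expect_equal(l1$contig_b, "c2"); expect_equal(l1$side_b, "begin")
  expect_equal(l1$orientation, "forward")
  expect_equal(l1$gap, 700)

  # a join properly aligned to a single contig contributes nothing
  single <- classify_proper(paf_row(query_len = 10000, query_start = 0,
                                    query_end = 6000, target_start = 44000,
                                    target_end = 50000))
  expect_equal(nrow(extract_links(single)), 0L)
})

test_that("a read spanning three contigs yields adjacent links plus
           skip-one evidence", {
  paf <- rbind(
    paf_row(query_id = "r1", query_len = 22000, query_start = 0,
            query_end = 6000, target_id = "c1", target_len = 30000,
            target_start = 24000, target_end = 30000, block_len = 6000),
    paf_row(query_id = "r1", query_len = 22000, query_start = 6300,
            query_end = 13300, target_id = "c2", target_len = 7000,
            target_start = 0, target_end = 7000, matches = 6900,
            block_len = 7000),
    paf_row(query_id = "r1", query_len = 22000, query_start = 13600,
            query_end = 21000, target_id = "c3", target_len = 40000,
            target_start = 0, target_end = 7400, matches = 7200,
            block_len = 7400))
  links <- extract_links(classify_proper(paf))
  expect_equal(sum(links$order == 1L), 2L)  # adjacent pairs only
  expect_equal(sum(links$order == 2L), 1L)  # c1-c3 evidence
  ev <- links[links$order == 2L, ]
  expect_setequal(c(ev$contig_a, ev$contig_b), c("c1", "c3"))
  # brute-force adjacent-pair enumeration: n proper alignments -> n-1 links
  expect_equal(sum(links$order == 1L), nrow(paf) - 1L)
})

test_that("bundle_links groups concordant links, enforces support,
           and takes the median gap", {
  base <- extract_links(classify_proper(make_spanning_paf()))
  mk <- function(join, gap) {
    l <- base[base$order == 1L, ]
    l$join_id <- join
    l$gap <- gap
    l
  }
  links <- rbind(mk("r1", 400), mk("r2", 500), mk("r3", 900))
  b <- bundle_links(links, min_support = 2)
  expect_equal(nrow(b), 1L)
  expect_equal(b$support, 3L)
  expect_equal(b$gap, 500)

  expect_equal(nrow(bundle_links(mk("r1", 400), min_support = 2)), 0L)
  expect_equal(nrow(bundle_links(mk("r1", 400), min_support = 1)), 1L)
})

test_that("proper-alignment invariants hold on randomized inputs", {
  set.seed(99)
  min_len <- 4000; max_ov <- 1000
  rows <- lapply(1:300, function(i) {
    tlen <- sample(3000:40000, 1)
    ts <- sample(0:(tlen - 1000), 1)
    te <- ts + sample(900:(tlen - ts), 1)
    qlen <- sample(2000:30000, 1)
    span <- min(te - ts, qlen)
    qs <- sample(0:(qlen - span), 1)
    paf_row(query_id = sprintf("r%03d", sample(1:60, 1)), query_len = qlen,
            query_start = qs, query_end = qs + span,
            strand = sample(c("+", "-"), 1), target_id =
              sprintf("c%02d", sample(1:12, 1)), target_len = tlen,
            target_start = ts, target_end = te, matches = span,
            block_len = span)
  })
  paf <- do.call(rbind, rows)
  cls <- classify_proper(paf, min_len, max_ov)
  pr <- cls[cls$status == "proper", ]
  expect_true(all(pr$block_len >= min_len))
  expect_true(all(pr$overhang <= max_ov))
  links <- extract_links(cls)
  if (nrow(links) > 0L) {
    n_proper <- table(pr$query_id)
    expect_true(all(n_proper[unique(links$join_id)] >= 2L))
  }
  b <- bundle_links(links, min_support = 2)
  if (nrow(b) > 0L) expect_true(all(b$support >= 2L))
})
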