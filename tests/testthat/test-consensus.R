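# patch_consensus: pileup consensus, re-anchoring, contained-contig
# absorption.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# bundle row + reads wrapping a set of junction interval sequences
fake_bundle <- function(seqs, flipped = FALSE) {
  ids <- sprintf("j%02d", seq_along(seqs))
  store <- if (flipped) revcomp(seqs) else seqs
  reads <- Biostrings::DNAStringSet(store)
  names(reads) <- ids
  b <- data.frame(bundle_id = "b1", contig_a = "ca", side_a = "end",
                  contig_b = "cb", side_b = "begin",
                  support = length(seqs), gap = 0,
                  stringsAsFactors = FALSE)
  b$members <- list(data.frame(join_id = ids, rstart = 0,
                               rend = nchar(store), flipped = flipped,
                               gap = 0, stringsAsFactors = FALSE))
  list(bundle = b, reads = reads)
}

test_that("consensus of identical intervals is the interval; flipped
           members are reverse-complemented back", {
  set.seed(1)
  s <- rand_seq(400)
  f <- fake_bundle(rep(s, 5))
  p <- build_patch(f$bundle, f$reads, mode = "ont")
  expect_equal(p$seq, s)
  expect_equal(p$support, 5L)

  f <- fake_bundle(rep(s, 4), flipped = TRUE)
  p <- build_patch(f$bundle, f$reads, mode = "ont")
  expect_equal(p$seq, s)
})

test_that("majority vote corrects a single-read substitution", {
  set.seed(2)
  s <- rand_seq(300)
  mut <- s
  substr(mut, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, 150, 150))[1L]
  f <- fake_bundle(c(rep(s, 4), mut))
  p <- build_patch(f$bundle, f$reads, mode = "ont")
  expect_equal(p$seq, s)
})

test_that("asm mode uses the single supporting interval verbatim, no
           consensus", {
  set.seed(3)
  s <- rand_seq(500)
  mut <- s
  substr(mut, 10, 10) <- "N"
  f <- fake_bundle(s)
  p <- build_patch(f$bundle, f$reads, mode = "asm", min_support = 1)
  expect_identical(p$seq, s)
})

test_that("consensus length lies within the member length range", {
  set.seed(4)
  base <- rand_seq(600)
  for (trial in 1:5) {
    seqs <- vapply(1:7, function(i) {
      s <- strsplit(base, "")[[1L]]
      drop <- sample(length(s), sample(0:20, 1))
      if (length(drop)) s <- s[-drop]
      paste(s, collapse = "")
    }, "")
    f <- fake_bundle(seqs)
    p <- build_patch(f$bundle, f$reads, mode = "ont")
    expect_gte(nchar(p$seq), min(nchar(seqs)) - 5)
    expect_lte(nchar(p$seq), max(nchar(seqs)) + 5)
  }
})

test_that("consensus of noisy reads beats any single read (known truth)", {
  for (seed in 1:5) {
    set.seed(seed)
    truth <- rand_seq(1000)
    noisy <- vapply(1:20, function(i)
      gapstitch:::apply_read_errors(truth, 0.05), "")
    f <- fake_bundle(noisy)
    p <- build_patch(f$bundle, f$reads, mode = "ont")
    idn <- function(q) {
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(truth),
        type = "global", substitutionMatrix =
          gapstitch:::consensus_submat(), gapOpening = 3, gapExtension = 1)
      gapstitch:::aln_identity(a)
    }
    cons_id <- idn(p$seq)
    read_ids <- vapply(noisy[1:8], idn, 0)
    expect_gt(cons_id, max(read_ids))
  }
})

make_anchor_fixture <- function(seed = 5, gap_len = 300, junk_right = 0) {
  set.seed(seed)
  ca <- rand_seq(3000); cb <- rand_seq(3000)
  gap <- rand_seq(gap_len)
  patch <- paste0(substr(ca, 2601, 3000), gap, substr(cb, 1, 400))
  if (junk_right > 0) ca <- paste0(ca, rand_seq(junk_right))
  contigs <- Biostrings::DNAStringSet(c(ca = ca, cb = cb))
  bundles <- data.frame(bundle_id = "b1", contig_a = "ca", side_a = "end",
                        contig_b = "cb", side_b = "begin", support = 5,
                        gap = gap_len, stringsAsFactors = FALSE)
  list(contigs = contigs, bundles = bundles, gap = gap,
       patches = list(b1 = list(seq = patch, support = 5)))
}

test_that("realign_patches anchors exact patches with zero trims and
           recovers the gap sequence", {
  fx <- make_anchor_fixture()
  out <- realign_patches(fx$patches, fx$bundles, fx$contigs)
  p <- out$b1
  expect_false(is.null(p))
  expect_equal(p$left_trim, 0L)
  expect_equal(p$right_trim, 0L)
  expect_equal(p$seq, fx$gap)
})

test_that("realign_patches trims a mis-assembled contig tip (within the
           overhang bound)", {
  fx <- make_anchor_fixture(junk_right = 300)
  out <- realign_patches(fx$patches, fx$bundles, fx$contigs)
  expect_equal(out$b1$left_trim, 300L)
  expect_equal(out$b1$seq, fx$gap)

  # junk beyond max_overhang: anchor sits too deep, junction demoted
  fx <- make_anchor_fixture(junk_right = 1400)
  out <- realign_patches(fx$patches, fx$bundles, fx$contigs)
  expect_null(out$b1)
})

test_that("a scrambled anchor demotes the patch to an unfilled gap", {
  fx <- make_anchor_fixture()
  set.seed(6)
  bad <- paste0(rand_seq(400), substr(fx$patches$b1$seq, 401,
                                      nchar(fx$patches$b1$seq)))
  out <- realign_patches(list(b1 = list(seq = bad, support = 5)),
                         fx$bundles, fx$contigs)
  expect_null(out$b1)
})

test_that("negative gaps are realised through trims when anchors overlap
           on the patch", {
  set.seed(7)
  ca <- rand_seq(3000)
  overlap <- 120
  cb <- paste0(substr(ca, 3000 - overlap + 1, 3000), rand_seq(2800))
  # the true junction overlaps by `overlap`; patch spans it seamlessly
  patch <- paste0(substr(ca, 2601, 3000), substr(cb, overlap + 1,
                                                 overlap + 400))
  contigs <- Biostrings::DNAStringSet(c(ca = ca, cb = cb))
  bundles <- data.frame(bundle_id = "b1", contig_a = "ca", side_a = "end",
                        contig_b = "cb", side_b = "begin", support = 4,
                        gap = -overlap, stringsAsFactors = FALSE)
  out <- realign_patches(list(b1 = list(seq = patch, support = 4)),
                         bundles, contigs)
  p <- out$b1
  expect_false(is.null(p))
  expect_equal(p$left_trim + p$right_trim + nchar(p$seq), overlap)
  # stitching reproduces the true merged sequence
  merged <- paste0(substr(ca, 1, 3000 - p$left_trim), p$seq,
                   substr(cb, p$right_trim + 1, nchar(cb)))
  truthm <- paste0(ca, substr(cb, overlap + 1, nchar(cb)))
  expect_equal(merged, truthm)
})

test_that("absorb_contained_contigs applies the unique 95/95 rule", {
  set.seed(8)
  pseq <- rand_seq(4000)
  patches <- list(p1 = list(seq = pseq, support = 5, left_trim = 0,
                            right_trim = 0, contig_a = "x", side_a = "end"))
  inner <- substr(pseq, 1001, 2800)  # 1800 bp, perfectly contained
  near <- gapstitch:::apply_read_errors(inner, 0.01)   # ~99% identity
  far <- gapstitch:::apply_read_errors(inner, 0.12)    # well below 95%
  contigs <- Biostrings::DNAStringSet(c(good = near, bad = far))
  out <- absorb_contained_contigs(patches, contigs, c("good", "bad"))
  expect_equal(out$removed$contig, "good")
  expect_equal(out$removed$patch_id, "p1")
  # the spliced patch now contains the contig byte-for-byte
  expect_true(grepl(near, out$patches$p1$seq, fixed = TRUE))

  # contained in two patches: left untouched
  patches2 <- list(p1 = patches$p1,
                   p2 = list(seq = paste0(rand_seq(500), inner,
                                          rand_seq(500)),
                             support = 3, left_trim = 0, right_trim = 0,
                             contig_a = "y", side_a = "end"))
  out2 <- absorb_contained_contigs(patches2,
                                   Biostrings::DNAStringSet(c(good = near)),
                                   "good")
  expect_equal(nrow(out2$removed), 0L)
})

test_that("absorbed splices keep the patch anchored (trim drift <= 50 bp)", {
  fx <- make_anchor_fixture(seed = 9, gap_len = 2500)
  anchored <- realign_patches(fx$patches, fx$bundles, fx$contigs)
  inner <- substr(anchored$b1$seq, 501, 2000)
  contigs2 <- c(fx$contigs, Biostrings::DNAStringSet(c(small = inner)))
  out <- absorb_contained_contigs(anchored, contigs2, "small")
  expect_equal(out$removed$contig, "small")
  # rebuild a raw patch from the refined core and re-anchor it
  refined <- list(b1 = list(
    seq = paste0(substr(as.character(fx$contigs[["ca"]]), 2601, 3000),
                 out$patches$b1$seq,
                 substr(as.character(fx$contigs[["cb"]]), 1, 400)),
    support = 5))
  re <- realign_patches(refined, fx$bundles, fx$contigs)
  expect_lte(abs(re$b1$left_trim - anchored$b1$left_trim), 50)
  expect_lte(abs(re$b1$right_trim - anchored$b1$right_trim), 50)
})
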