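# Shared fixtures: built in code, no binary data.

paf_row <- function(query_id = "r1", query_len = 10000, query_start = 0,
                    query_end = 6000, strand = "+", target_id = "c1",
                    target_len = 50000, target_start = 44000,
                    target_end = 50000, matches = 5800, block_len = 6000,
                    mapq = 60) {
  data.frame(query_id = query_id, query_len = query_len,
             query_start = query_start, query_end = query_end,
             strand = strand, target_id = target_id,
             target_len = target_len, target_start = target_start,
             target_end = target_end, matches = matches,
             block_len = block_len, mapq = mapq, stringsAsFactors = FALSE)
}

fig3_graph <- function() {
  read_graph_tsv(system.file("extdata", "fig3_graph.tsv",
                             package = "gapstitch", mustWork = TRUE))
}

path_signatures <- function(paths) {
  sort(vapply(paths, gapstitch:::chain_signature, ""))
}

# Random side-typed graph with <= 12 nodes; no same-side self loops, at
# most one edge per end pair.
rand_graph <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  ids <- sprintf("n%02d", seq_len(n))
  lens <- stats::setNames(sample(1000:20000, n, replace = TRUE), ids)
  m <- sample(0:(n + 4), 1)
  edges <- NULL
  if (m > 0) {
    keys <- character(0)
    for (i in seq_len(m)) {
      a <- sample(ids, 1); b <- sample(ids, 1)
      sa <- sample(c("begin", "end"), 1); sb <- sample(c("begin", "end"), 1)
      if (a == b && sa == sb) next
      k <- paste(sort(paste0(c(a, b), "|", c(sa, sb))), collapse = "~")
      if (k %in% keys) next
      keys <- c(keys, k)
      edges <- rbind(edges, data.frame(
        node1 = a, side1 = sa, node2 = b, side2 = sb,
        support = sample(1:5, 1), gap = sample(100:800, 1),
        stringsAsFactors = FALSE))
    }
  }
  build_graph(lens, edges)
}

# A small simulated scaffolding scenario (genome -> contigs -> reads).
sim_scenario <- function(seed, genome_len = 60000, n_contigs = 6,
                         coverage = 20, read_len = 9000, error_rate = 0,
                         gap_range = c(200, 800), repeat_count = 0,
                         repeat_len = 8000, end_perturb_bp = 0) {
  truth <- simulate_genome(genome_len, repeat_count = repeat_count,
                           repeat_len = repeat_len, seed = seed)
  fr <- fragment_genome(truth, n_contigs, gap_range = gap_range,
                        seed = seed + 1, end_perturb_bp = end_perturb_bp)
  rd <- simulate_reads(fr$truth, coverage, read_len_mean = read_len,
                       error_rate = error_rate, seed = seed + 2)
  dir <- tempfile("scenario_")
  dir.create(dir)
  contigs_fa <- file.path(dir, "contigs.fa")
  reads_fa <- file.path(dir, "reads.fa")
  write_fasta(fr$contigs, contigs_fa)
  write_fasta(rd$reads, reads_fa)
  list(truth = rd$truth, contigs = fr$contigs, reads = rd$reads,
       contigs_fa = contigs_fa, reads_fa = reads_fa, dir = dir)
}

# Scenario with a collapsed repeat: the genome carries one exact repeat at
# two loci but the input assembly contains the repeat contig only once
# (as an assembler would collapse it), flanked by unique contigs.
repeat_scenario <- function(seed, genome_len = 200000, repeat_len = 8000,
                            coverage = 20, read_len = 18000, gap = 300) {
  truth <- simulate_genome(genome_len, repeat_count = 2,
                           repeat_len = repeat_len, repeat_identity = 1,
                           seed = seed, min_separation = 50000)
  A <- truth$repeats$start[1]; B <- truth$repeats$start[2]
  g <- truth$genome
  segs <- list(
    U1 = c(0, A - gap),
    R = c(A, A + repeat_len),
    U2 = c(A + repeat_len + gap, B - gap),
    U3 = c(B + repeat_len + gap, genome_len))
  seqs <- vapply(segs, function(s) substr(g, s[1] + 1, s[2]), "")
  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- names(segs)
  # truth placements: R recorded at its first locus
  truth$contigs <- data.frame(
    id = names(segs),
    start = vapply(segs, `[[`, 0, 1), end = vapply(segs, `[[`, 0, 2),
    orient = "+", perturb_right = 0L, stringsAsFactors = FALSE)
  rd <- simulate_reads(truth, coverage, read_len_mean = read_len,
                       error_rate = 0, seed = seed + 2)
  dir <- tempfile("repeat_scenario_")
  dir.create(dir)
  contigs_fa <- file.path(dir, "contigs.fa")
  reads_fa <- file.path(dir, "reads.fa")
  write_fasta(contigs, contigs_fa)
  write_fasta(rd$reads, reads_fa)
  list(truth = rd$truth, contigs = contigs, reads = rd$reads,
       contigs_fa = contigs_fa, reads_fa = reads_fa, dir = dir)
}

run_scenario <- function(sc, mode = "ont", min_aln_len = 2500,
                         min_support = 2, ...) {
  cfg <- run_config(sc$contigs_fa, sc$reads_fa, mode = mode,
                    min_aln_len = min_aln_len, min_support = min_support,
                    out_prefix = file.path(sc$dir, "out", "run"), ...)
  suppressWarnings(scaffold_run(cfg))
}
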