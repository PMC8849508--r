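# Synthetic genomes, fragmented assemblies and long reads with known truth.
#
# All generators are deterministic given their seed and leave the caller's
# RNG stream untouched. The error model is i.i.d. substitutions, insertions
# and deletions in 1:1:1 ratio at the stated total per-base rate;
# homopolymer-biased errors are deliberately not modelled.

DNA_BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                              collapse = "")

mutate_to_identity <- function(seq, identity) {
  if (identity >= 1) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut == 0L) return(seq)
  pos <- sample(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with interspersed repeats
#'
#' Generates an i.i.d. uniform ACGT background and plants `repeat_count`
#' copies of a single repeat unit at random, non-adjacent positions, each
#' copy mutated to `repeat_identity`.
#'
#' @param length genome length in bp.
#' @param repeat_count number of repeat copies (0 for none).
#' @param repeat_len repeat unit length in bp.
#' @param repeat_identity per-copy identity to the unit (1 = exact).
#' @param seed integer RNG seed.
#' @param min_separation minimum distance between repeat copies and from
#'   the genome ends (default 2000 bp).
#' @return a truth object (list) with elements `genome` (character),
#'   `genome_len`, `repeats` (`data.frame` of 0-based `start`, `end`,
#'   `copy_group`), and empty `contigs`/`reads` slots.
#' @export
simulate_genome <- function(length, repeat_count = 0L, repeat_len = 0L,
                            repeat_identity = 1, seed = 1L,
                            min_separation = 2000L) {
  stopifnot(length >= 1)
  if (repeat_count > 0L && repeat_len * repeat_count >= length / 2)
    stop("repeat_len * repeat_count must be < length/2")
  with_seed(seed, {
    genome <- rand_dna(length)
    repeats <- data.frame(start = numeric(0), end = numeric(0),
                          copy_group = integer(0))
    if (repeat_count > 0L) {
      unit <- rand_dna(repeat_len)
      placed <- numeric(0)
      tries <- 0L
      while (base::length(placed) < repeat_count) {
        tries <- tries + 1L
        if (tries > 1000L) stop("could not place repeats after 1000 tries")
        s <- sample.int(length - repeat_len - min_separation, 1L) +
          min_separation %/% 2
        if (all(abs(s - placed) >= repeat_len + min_separation)) {
          placed <- c(placed, s)
        }
      }
      placed <- sort(placed)
      for (i in seq_along(placed)) {
        copy <- mutate_to_identity(unit, repeat_identity)
        substr(genome, placed[i] + 1L, placed[i] + repeat_len) <- copy
        repeats <- rbind(repeats, data.frame(
          start = placed[i], end = placed[i] + repeat_len, copy_group = 1L))
      }
    }
    list(genome = genome, genome_len = length, repeats = repeats,
         contigs = NULL, reads = NULL)
  })
}

#' Fragment a simulated genome into gapped contigs
#'
#' Tiles the genome with `n_contigs` contigs separated by gaps drawn
#' uniformly from `gap_range`. A fraction of contigs is emitted
#' reverse-complemented to exercise orientation handling, and an optional
#' end perturbation appends shuffled sequence to the right (genome-frame)
#' end of each internal contig to exercise overhang trimming.
#'
#' @param truth a truth object from [simulate_genome()].
#' @param n_contigs number of contigs.
#' @param gap_range numeric length-2, inclusive bp range of inter-contig
#'   gaps.
#' @param seed integer RNG seed.
#' @param revcomp_frac fraction of contigs emitted reverse-complemented.
#' @param end_perturb_bp bp of shuffled sequence appended at internal
#'   right ends (0 disables; at most 1000).
#' @return list `(contigs, truth)`: a named [Biostrings::DNAStringSet] and
#'   the truth updated with 0-based contig placements (`id`, `start`,
#'   `end`, `orient`, `perturb_right`).
#' @export
fragment_genome <- function(truth, n_contigs, gap_range = c(200, 1500),
                            seed = 1L, revcomp_frac = 0.25,
                            end_perturb_bp = 0L) {
  L <- truth$genome_len
  stopifnot(n_contigs >= 1, end_perturb_bp <= 1000)
  max_gap_total <- (n_contigs - 1L) * gap_range[2L]
  if (max_gap_total >= L)
    stop("n_contigs incompatible with gap_range: gaps cannot exceed genome")
  with_seed(seed, {
    gaps <- if (n_contigs > 1L)
      round(stats::runif(n_contigs - 1L, gap_range[1L], gap_range[2L]))
    else numeric(0)
    avail <- L - sum(gaps)
    if (avail < n_contigs) stop("n_contigs incompatible with gap_range")
    base_len <- avail / n_contigs
    jitter <- stats::runif(n_contigs, 0.8, 1.2)
    lens <- pmax(1, round(base_len * jitter / sum(jitter) * n_contigs))
    lens[n_contigs] <- avail - sum(lens[-n_contigs])
    starts <- cumsum(c(0, head(lens, -1L) + gaps))
    ids <- sprintf("ctg%03d", seq_len(n_contigs))
    orient <- rep("+", n_contigs)
    n_rev <- round(revcomp_frac * n_contigs)
    if (n_rev > 0L) orient[sample.int(n_contigs, n_rev)] <- "-"
    seqs <- character(n_contigs)
    perturb <- rep(0L, n_contigs)
    for (i in seq_len(n_contigs)) {
      s <- substr(truth$genome, starts[i] + 1L, starts[i] + lens[i])
      if (end_perturb_bp > 0L && i < n_contigs) {
        junk <- paste(sample(strsplit(substr(s, 1L, end_perturb_bp),
                                      "")[[1L]]), collapse = "")
        s <- paste0(s, junk)
        perturb[i] <- end_perturb_bp
      }
      seqs[i] <- if (orient[i] == "-") revcomp(s) else s
    }
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- ids
    truth$contigs <- data.frame(
      id = ids, start = starts, end = starts + lens, orient = orient,
      perturb_right = perturb, stringsAsFactors = FALSE)
    list(contigs = contigs, truth = truth)
  })
}

apply_read_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  p <- error_rate / 3
  kind <- sample.int(4L, n, replace = TRUE,
                     prob = c(1 - error_rate, p, p, p))
  # 1 = keep, 2 = substitution, 3 = insertion after, 4 = deletion
  out <- chars
  subs <- which(kind == 2L)
  for (i in subs) out[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  ins <- which(kind == 3L)
  if (length(ins) > 0L)
    out[ins] <- paste0(out[ins], sample(DNA_BASES, length(ins),
                                        replace = TRUE))
  out[kind == 4L] <- ""
  paste(out, collapse = "")
}

#' Simulate long reads from a genome
#'
#' Read start positions are uniform, lengths log-normal around
#' `read_len_mean` (sdlog 0.25), strands random, and errors i.i.d.
#' substitutions/insertions/deletions in 1:1:1 ratio at `error_rate`.
#'
#' @param truth a truth object with a `genome`.
#' @param coverage requested fold coverage.
#' @param read_len_mean mean read length in bp.
#' @param error_rate total per-base error rate (0 for error-free reads).
#' @param seed integer RNG seed.
#' @param min_len minimum read length kept (default 500 bp).
#' @return list `(reads, truth)`: a named [Biostrings::DNAStringSet] and
#'   the truth updated with read placements (`id`, `start`, `end`,
#'   `strand`, `error_rate`), 0-based genome coordinates.
#' @export
simulate_reads <- function(truth, coverage, read_len_mean = 15000,
                           error_rate = 0, seed = 1L, min_len = 500L) {
  L <- truth$genome_len
  with_seed(seed, {
    n <- ceiling(coverage * L / read_len_mean)
    sdlog <- 0.25
    lens <- round(stats::rlnorm(n, log(read_len_mean) - sdlog^2 / 2, sdlog))
    lens <- clamp(lens, min_len, L)
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L, 0)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("read%05d", seq_len(n))
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- substr(truth$genome, starts[i] + 1L, starts[i] + lens[i])
      if (strands[i] == "-") s <- revcomp(s)
      seqs[i] <- apply_read_errors(s, error_rate)
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    truth$reads <- data.frame(
      id = ids, start = starts, end = starts + lens, strand = strands,
      error_rate = error_rate, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Write a truth object as TSV
#'
#' Sections are marked by a leading column: `contig` and `read` placement
#' rows plus a `genome` header row. Version 1.
#'
#' @param truth truth object.
#' @param path output TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("#truth_tsv\tv1\n", file = con)
  cat(sprintf("genome\t%d\n", truth$genome_len), file = con)
  if (!is.null(truth$contigs)) {
    for (i in seq_len(nrow(truth$contigs))) {
      c <- truth$contigs[i, ]
      cat(sprintf("contig\t%s\t%d\t%d\t%s\t%d\n", c$id, c$start, c$end,
                  c$orient, c$perturb_right), file = con)
    }
  }
  if (!is.null(truth$reads)) {
    for (i in seq_len(nrow(truth$reads))) {
      r <- truth$reads[i, ]
      cat(sprintf("read\t%s\t%d\t%d\t%s\t%g\n", r$id, r$start, r$end,
                  r$strand, r$error_rate), file = con)
    }
  }
  invisible(path)
}
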