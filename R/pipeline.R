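# End-to-end orchestration: align -> filter -> bundle -> consensus ->
# re-align -> graph -> resolve -> absorb -> emit.

#' Build a run configuration
#'
#' Defaults follow the method's stated parameters: minimum proper-alignment
#' length 5000 bp, maximum overhang 1000 bp, and minimum support of 2 for
#' deep read coverage (`ont`/`pbclr`) or 1 when joining with another
#' assembly (`asm`).
#'
#' @param assembly path to the assembly FASTA (contigs or scaffolds).
#' @param joins path to the joining sequences (long reads or a second
#'   assembly), FASTA/FASTQ, optionally gzipped.
#' @param mode data type of the joining sequences: `"ont"`, `"pbclr"` or
#'   `"asm"`.
#' @param min_aln_len minimum proper-alignment block length (bp).
#' @param max_overhang maximum contig-end overhang (bp).
#' @param min_support minimum links per bundle; `NULL` selects the mode
#'   default (2 for read modes, 1 for `asm`).
#' @param anchor_bp flanking anchor for patch re-alignment (bp).
#' @param threads aligner threads.
#' @param seed RNG seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @param out_prefix output path prefix; `NULL` for a temp directory.
#' @param paf optional precomputed PAF (skips the aligner).
#' @param fill_gaps build consensus patches (TRUE) or emit N-gaps only.
#' @return an object of class `gapstitch_config`.
#' @export
run_config <- function(assembly, joins, mode = c("ont", "pbclr", "asm"),
                       min_aln_len = 5000, max_overhang = 1000,
                       min_support = NULL, anchor_bp = 200, threads = 1L,
                       seed = 1L, out_prefix = NULL, paf = NULL,
                       fill_gaps = TRUE) {
  mode <- match.arg(mode)
  if (is.null(min_support)) min_support <- if (mode == "asm") 1L else 2L
  if (!file.exists(assembly)) stop("assembly file not found: ", assembly)
  if (!file.exists(joins)) stop("joins file not found: ", joins)
  if (!is.null(paf) && !file.exists(paf)) stop("PAF file not found: ", paf)
  stopifnot(min_aln_len > 0, max_overhang > 0, min_support >= 1,
            anchor_bp > 0, threads >= 1)
  if (is.null(out_prefix))
    out_prefix <- file.path(tempfile("gapstitch_run_"), "out")
  structure(list(assembly = assembly, joins = joins, mode = mode,
                 min_aln_len = min_aln_len, max_overhang = max_overhang,
                 min_support = min_support, anchor_bp = anchor_bp,
                 threads = threads, seed = seed, out_prefix = out_prefix,
                 paf = paf, fill_gaps = fill_gaps),
            class = "gapstitch_config")
}

#' Run the scaffolding pipeline
#'
#' Executes the full method and writes, under `out_prefix`: the scaffold
#' FASTA and AGP, a junction report, the patch FASTA and patch report, the
#' removed-haplotigs FASTA, the absorbed-contigs report, and a run log
#' with every parameter and per-stage counts. The alignment stage result is
#' cached next to the outputs keyed by a content hash of its inputs, so
#' re-runs skip the aligner.
#'
#' @param config a `gapstitch_config` from [run_config()].
#' @return an object of class `gapstitch_result`: a list with `scaffolds`,
#'   `paths`, `patches`, `haplotigs`, `repeat_info`, `absorbed`, `stats`,
#'   `accounting` and `files`.
#' @export
scaffold_run <- function(config) {
  stopifnot(inherits(config, "gapstitch_config"))
  dir.create(dirname(config$out_prefix), recursive = TRUE,
             showWarnings = FALSE)
  files <- list(
    log = paste0(config$out_prefix, ".log"),
    scaffolds = paste0(config$out_prefix, ".scaffolds.fasta"),
    agp = paste0(config$out_prefix, ".scaffolds.agp"),
    junctions = paste0(config$out_prefix, ".junctions.tsv"),
    patches = paste0(config$out_prefix, ".patches.fasta"),
    patch_report = paste0(config$out_prefix, ".patches.tsv"),
    haplotigs = paste0(config$out_prefix, ".haplotigs.fasta"),
    absorbed = paste0(config$out_prefix, ".absorbed.tsv"))
  if (file.exists(files$log)) unlink(files$log)
  log <- files$log
  stage <- "load"
  res <- tryCatch({
    for (p in names(config))
      vlog(log, "param %s = %s", p,
           paste(format(config[[p]]), collapse = " "))
    contigs <- read_fasta(config$assembly)
    joins <- read_fasta(config$joins)
    vlog(log, "loaded %d contigs (%d bp), %d joining sequences",
         length(contigs), sum(Biostrings::width(contigs)), length(joins))
    assembly_n90 <- n90(as.numeric(Biostrings::width(contigs)))
    if (!is.na(assembly_n90) && assembly_n90 < config$min_aln_len) {
      warning("input assembly N90 (", assembly_n90, " bp) is below ",
              "min_aln_len (", config$min_aln_len, " bp); the method ",
              "performs best on relatively contiguous assemblies ",
              "(N90 > 10 kb)", call. = FALSE)
      vlog(log, "WARNING: assembly N90 %d below min_aln_len %d",
           assembly_n90, config$min_aln_len)
    }

    stage <- "align"
    paf_path <- config$paf
    if (is.null(paf_path)) {
      paf_path <- paste0(config$out_prefix, ".paf")
      hash_path <- paste0(paf_path, ".hash")
      hash <- paste(tools::md5sum(c(config$assembly, config$joins)),
                    config$mode, collapse = " ")
      if (!(file.exists(paf_path) && file.exists(hash_path) &&
            identical(readLines(hash_path, warn = FALSE), hash))) {
        run_aligner(config$assembly, config$joins, config$mode,
                    threads = config$threads, out_paf = paf_path)
        writeLines(hash, hash_path)
      } else {
        vlog(log, "alignment cache hit: %s", paf_path)
      }
    }
    paf <- parse_paf(paf_path)
    vlog(log, "alignments in: %d", nrow(paf))
    if (length(joins) == 0L || nrow(paf) == 0L)
      warning("no alignments between joins and contigs; ",
              "output equals the input assembly", call. = FALSE)

    stage <- "filter"
    best <- select_best(paf)
    cls <- classify_proper(best, config$min_aln_len, config$max_overhang)
    proper <- cls[cls$status == "proper", , drop = FALSE]
    vlog(log, "best alignments: %d; proper: %d", nrow(best), nrow(proper))

    stage <- "link"
    links <- extract_links(cls, anchor_bp = config$anchor_bp)
    bundles <- bundle_links(links, min_support = config$min_support,
                            order = 1L)
    evidence <- bundle_links(links, min_support = config$min_support,
                             order = 2L)
    vlog(log, "links: %d; bundles (support >= %d): %d; evidence bundles: %d",
         sum(links$order == 1L), config$min_support, nrow(bundles),
         nrow(evidence))

    stage <- "consensus"
    patches_raw <- stats::setNames(vector("list", nrow(bundles)),
                                   bundles$bundle_id)
    if (config$fill_gaps && nrow(bundles) > 0L) {
      for (i in seq_len(nrow(bundles))) {
        patches_raw[[i]] <- build_patch(bundles[i, , drop = FALSE], joins,
                                        mode = config$mode,
                                        min_support = config$min_support)
      }
    }
    vlog(log, "patches built: %d / %d",
         sum(!vapply(patches_raw, is.null, TRUE)), nrow(bundles))

    stage <- "realign"
    anchored <- realign_patches(patches_raw, bundles, contigs,
                                max_overhang = config$max_overhang,
                                anchor_bp = config$anchor_bp)
    vlog(log, "patches anchored: %d / %d",
         sum(!vapply(anchored, is.null, TRUE)), nrow(bundles))

    stage <- "graph"
    edges <- if (nrow(bundles) > 0L)
      data.frame(node1 = bundles$contig_a, side1 = bundles$side_a,
                 node2 = bundles$contig_b, side2 = bundles$side_b,
                 support = bundles$support, gap = bundles$gap,
                 patch_id = bundles$bundle_id, stringsAsFactors = FALSE)
      else NULL
    g <- build_graph(contigs, edges)
    resolved <- resolve_graph(g, evidence = evidence)
    paths <- resolved$paths
    vlog(log, "graph: %d nodes, %d edges -> %d paths; %d haplotigs; %d repeats",
         length(g$nodes), nrow(g$edges), length(paths),
         nrow(resolved$haplotigs), nrow(resolved$repeat_info))
    for (pid in resolved$dropped_patches) anchored[[pid]] <- NULL

    stage <- "absorb"
    singleton <- vapply(paths, function(ch) nrow(ch$members) == 1L, TRUE)
    rep_members <- unlist(strsplit(resolved$repeat_info$members, ","))
    cand <- vapply(paths[singleton], function(ch) ch$members$id[1L], "")
    cand <- setdiff(cand, rep_members)
    abs_res <- absorb_contained_contigs(anchored, contigs, cand)
    anchored <- abs_res$patches
    absorbed <- abs_res$removed
    if (nrow(absorbed) > 0L) {
      keep <- vapply(paths, function(ch) {
        nrow(ch$members) > 1L || !(ch$members$id[1L] %in% absorbed$contig)
      }, TRUE)
      paths <- paths[keep]
    }
    vlog(log, "absorbed contigs: %d", nrow(absorbed))

    stage <- "emit"
    out <- write_scaffolds(paths, anchored, contigs,
                           out_fasta = files$scaffolds, out_agp = files$agp,
                           out_junctions = files$junctions)
    # patch FASTA + report
    if (length(out$patch_components) > 0L) {
      write_fasta(Biostrings::DNAStringSet(unlist(out$patch_components)),
                  files$patches)
    } else writeLines(character(0), files$patches)
    patch_report <- patch_report_df(anchored, absorbed)
    utils::write.table(patch_report, files$patch_report, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hap <- resolved$haplotigs
    if (nrow(hap) > 0L) {
      write_fasta(contigs[hap$contig], files$haplotigs)
    } else writeLines(character(0), files$haplotigs)
    utils::write.table(absorbed, files$absorbed, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    accounting <- accounting_identity(out, contigs, paths)
    vlog(log, "scaffolds: %d (%d bp); accounting lhs %d rhs %d",
         length(out$scaffolds), sum(Biostrings::width(out$scaffolds)),
         accounting$lhs, accounting$rhs)
    stats <- list(
      n_contigs = length(contigs), n_joins = length(joins),
      alignments = nrow(paf), best = nrow(best), proper = nrow(proper),
      links = nrow(links), bundles = nrow(bundles),
      patches_built = sum(!vapply(patches_raw, is.null, TRUE)),
      patches_anchored = sum(!vapply(anchored, is.null, TRUE)),
      paths = length(paths), haplotigs = nrow(hap),
      repeats = nrow(resolved$repeat_info), absorbed = nrow(absorbed),
      assembly_n90 = assembly_n90)
    structure(list(scaffolds = out$scaffolds, paths = paths,
                   patches = anchored, haplotigs = hap,
                   repeat_info = resolved$repeat_info, absorbed = absorbed,
                   agp = out$agp, junctions = out$junctions,
                   stats = stats, accounting = accounting, files = files,
                   config = config),
              class = "gapstitch_result")
  }, error = function(e) {
    for (f in files) {
      if (f != files$log && file.exists(f)) file.rename(f, paste0(f, ".partial"))
    }
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' @export
print.gapstitch_result <- function(x, ...) {
  cat("gapstitch result:", length(x$scaffolds), "scaffolds,",
      sum(Biostrings::width(x$scaffolds)), "bp\n")
  cat("  N50:", n50(as.numeric(Biostrings::width(x$scaffolds))), "bp\n")
  cat("  haplotigs removed:", nrow(x$haplotigs),
      "| repeats:", nrow(x$repeat_info),
      "| absorbed:", nrow(x$absorbed), "\n")
  invisible(x)
}

patch_report_df <- function(anchored, absorbed) {
  live <- names(anchored)[!vapply(anchored, is.null, TRUE)]
  if (length(live) == 0L) {
    return(data.frame(junction = character(0), support = integer(0),
                      patch_length = integer(0), left_trim = integer(0),
                      right_trim = integer(0), absorbed = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    junction = live,
    support = vapply(live, function(k) anchored[[k]]$support, 0),
    patch_length = vapply(live, function(k) nchar(anchored[[k]]$seq), 0),
    left_trim = vapply(live, function(k) anchored[[k]]$left_trim, 0),
    right_trim = vapply(live, function(k) anchored[[k]]$right_trim, 0),
    absorbed = vapply(live, function(k)
      paste(absorbed$contig[absorbed$patch_id == k], collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Byte accounting: scaffold bases must equal member contig bases minus
# trimmed bases plus patch bases plus N-gap bases.
accounting_identity <- function(out, contigs, paths) {
  lhs <- sum(Biostrings::width(out$scaffolds))
  member_bp <- 0; trim_bp <- 0
  for (ch in paths)
    member_bp <- member_bp +
      sum(as.numeric(Biostrings::width(contigs[ch$members$id])))
  a <- out$agp
  patch_bp <- 0; gap_bp <- 0
  if (!is.null(a)) {
    w <- a$component_type == "W"
    ctg <- w & a$component_id %in% names(contigs)
    pat <- w & !ctg
    used <- sum(a$component_end[ctg] - a$component_beg[ctg] + 1)
    trim_bp <- member_bp - used
    patch_bp <- sum(a$object_end[pat] - a$object_beg[pat] + 1)
    gap_bp <- sum(a$object_end[!w] - a$object_beg[!w] + 1)
  }
  list(lhs = as.integer(lhs),
       rhs = as.integer(member_bp - trim_bp + patch_bp + gap_bp),
       member_bp = member_bp, trim_bp = trim_bp, patch_bp = patch_bp,
       gap_bp = gap_bp)
}
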