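# Invocation of the external long-read aligner (minimap2).

#' Align joining sequences to contigs with minimap2
#'
#' Runs minimap2 with the preset matching the data type: `ont` uses the
#' noisy-long-read preset `map-ont`, `pbclr` the PacBio CLR preset
#' `map-pb`, and `asm` (a second assembly or HiFi reads) the
#' assembly-to-assembly preset `asm20`. A precomputed PAF may be supplied
#' anywhere the pipeline calls this, in which case minimap2 is not needed.
#'
#' @param contigs path to the assembly FASTA (targets).
#' @param joins path to the joining-sequence FASTA/FASTQ (queries).
#' @param mode one of `"ont"`, `"pbclr"`, `"asm"`.
#' @param threads number of aligner threads.
#' @param out_paf output PAF path (default: a temp file).
#' @return the PAF path, invisibly.
#' @export
run_aligner <- function(contigs, joins, mode = c("ont", "pbclr", "asm"),
                        threads = 1L, out_paf = tempfile(fileext = ".paf")) {
  mode <- match.arg(mode)
  if (Sys.which("minimap2") == "") {
    stop("configuration error: minimap2 not found on PATH. Either install ",
         "minimap2 or supply a precomputed PAF of the joining sequences ",
         "aligned to the contigs (paf = <file> / --paf).", call. = FALSE)
  }
  if (!file.exists(contigs)) stop("contigs file not found: ", contigs)
  if (!file.exists(joins)) stop("joins file not found: ", joins)
  if (file.size(joins) == 0L) {  # minimap2 rejects empty query files
    writeLines(character(0), out_paf)
    return(invisible(out_paf))
  }
  preset <- switch(mode, ont = "map-ont", pbclr = "map-pb", asm = "asm20")
  args <- c("-x", preset, "-t", as.character(threads),
            "--secondary=yes", contigs, joins)
  status <- system2("minimap2", args, stdout = out_paf,
                    stderr = tempfile(fileext = ".mm2.log"))
  if (status != 0L) stop("minimap2 failed with exit status ", status)
  invisible(out_paf)
}
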