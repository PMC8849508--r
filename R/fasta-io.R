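# FASTA/FASTQ input and output.
#
# Sequence sets are carried as named Biostrings::DNAStringSet objects over
# the 5-letter alphabet {A,C,G,T,N}: input is uppercased and any other
# letter (IUPAC ambiguity codes and the like) is mapped to N with a warning,
# because alignment filtering and the pileup consensus operate on a
# 5-letter alphabet.

#' Read sequences from FASTA or FASTQ
#'
#' Auto-detects FASTA vs FASTQ from the first byte (`>` vs `@`); gzip
#' compression is handled transparently. The description after the first
#' whitespace is dropped from each id. Sequences are uppercased and
#' non-ACGTN letters are replaced by N (with a warning).
#'
#' @param path path to a FASTA or FASTQ file, optionally gzip-compressed.
#' @return a named [Biostrings::DNAStringSet]; ids are unique.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 a contig", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "r")
  first <- tryCatch(readLines(con, n = 1L, warn = FALSE), finally = close(con))
  if (length(first) == 0L) {
    return(stats::setNames(Biostrings::DNAStringSet(), character(0)))
  }
  byte <- substr(first, 1L, 1L)
  fmt <- switch(byte, ">" = "fasta", "@" = "fastq",
                stop("parse error at line 1 of ", path,
                     ": expected '>' (FASTA) or '@' (FASTQ), saw '", byte, "'"))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) stop("malformed ", fmt, " in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    warning(sum(bad), " record(s) in ", path,
            " contain non-ACGTN letters; mapped to N")
    chr[bad] <- gsub("[^ACGTN]", "N", chr[bad])
  }
  if (any(nchar(chr) == 0L)) {
    stop("zero-length sequence in ", path, ": ",
         paste(ids[nchar(chr) == 0L], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named [Biostrings::DNAStringSet] or named character vector.
#' @param path output file path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) > 0 && is.null(names(seqs)))
    stop("sequences must be named")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
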