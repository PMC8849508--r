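# Internal helpers shared across modules.

#' Reverse-complement nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors over the ACGTN alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Contiguity statistics (Nx / NGx)
#'
#' `nx_stat()` returns the length L such that sequences of length >= L cover
#' at least `frac` of `total`. With `total = sum(lengths)` this is the
#' classical N50 (at `frac = 0.5`); passing a reference genome size as
#' `total` gives NG50.
#'
#' @param lengths numeric vector of sequence lengths.
#' @param frac fraction of `total` to cover (0.5 for N50, 0.9 for N90).
#' @param total the denominator; defaults to `sum(lengths)`.
#' @return a single length in bp, or `NA` if `total` cannot be covered.
#' @export
nx_stat <- function(lengths, frac = 0.5, total = sum(lengths)) {
  if (length(lengths) == 0L || total <= 0) return(NA_real_)
  ls <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(ls)
  idx <- which(cum >= frac * total)
  if (length(idx) == 0L) return(NA_real_)
  ls[idx[1L]]
}

#' @rdname nx_stat
#' @export
n50 <- function(lengths) nx_stat(lengths, 0.5)

#' @rdname nx_stat
#' @export
n90 <- function(lengths) nx_stat(lengths, 0.9)

#' @rdname nx_stat
#' @param genome_size reference genome size in bp.
#' @export
ng50 <- function(lengths, genome_size) nx_stat(lengths, 0.5, total = genome_size)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

other_side <- function(side) ifelse(side == "begin", "end", "begin")

# End keys identify one extremity of a node: "<id>|begin" / "<id>|end".
end_key <- function(id, side) paste0(id, "|", side)

split_end_key <- function(key) {
  pos <- regexpr("\\|[^|]*$", key)
  list(id = substr(key, 1L, pos - 1L),
       side = substr(key, pos + 1L, nchar(key)))
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Percent identity of a pairwiseAlignment as matches / alignment columns.
aln_identity <- function(aln) {
  w <- Biostrings::nchar(Biostrings::alignedPattern(aln))
  if (w == 0L) return(0)
  Biostrings::nmatch(aln) / w
}

# Stage logging: always appended to the run log file; echoed to the
# console only under options(gapstitch.verbose = TRUE) (set by the CLI).
vlog <- function(log, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE, sep = "")
  if (isTRUE(getOption("gapstitch.verbose", FALSE))) message(msg)
  invisible(msg)
}
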