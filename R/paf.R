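# PAF (Pairwise mApping Format) parsing and writing.
#
# PAF is the alignment interchange format throughout: minimap2 emits it and
# every downstream stage consumes the 12 mandatory columns. Coordinates are
# kept in PAF's native convention, 0-based half-open, everywhere inside the
# package; only the AGP writer converts at the boundary.

paf_cols <- c("query_id", "query_len", "query_start", "query_end", "strand",
              "target_id", "target_len", "target_start", "target_end",
              "matches", "block_len", "mapq")

#' Parse PAF alignments
#'
#' Accepts a file path or a character vector of PAF lines. Only the 12
#' mandatory columns are kept; trailing optional tags are ignored.
#' Coordinates are 0-based half-open on the forward strand of each sequence
#' (PAF convention): for `-` strand alignments `query_start`/`query_end`
#' still refer to the forward query.
#'
#' @param x path to a PAF file, or a character vector of lines.
#' @return a `data.frame` with columns `query_id`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target_id`, `target_len`,
#'   `target_start`, `target_end`, `matches`, `block_len`, `mapq`.
#' @export
parse_paf <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x))
    readLines(x) else x
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("PAF parse error at line ", which(nf < 12L)[1L],
         ": expected >= 12 tab-separated columns, found ", nf[nf < 12L][1L])
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, name) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("PAF parse error at line ", bad, ": non-integer ", name)
    }
    v
  }
  df <- data.frame(
    query_id = col(1), query_len = num(2, "query_len"),
    query_start = num(3, "query_start"), query_end = num(4, "query_end"),
    strand = col(5),
    target_id = col(6), target_len = num(7, "target_len"),
    target_start = num(8, "target_start"), target_end = num(9, "target_end"),
    matches = num(10, "matches"), block_len = num(11, "block_len"),
    mapq = num(12, "mapq"),
    stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("PAF parse error at line ", which(!df$strand %in% c("+", "-"))[1L],
         ": strand must be '+' or '-'")
  }
  bad <- df$query_start < 0 | df$query_start >= df$query_end |
    df$query_end > df$query_len |
    df$target_start < 0 | df$target_start >= df$target_end |
    df$target_end > df$target_len
  if (any(bad)) {
    stop("PAF parse error at line ", which(bad)[1L],
         ": coordinates violate 0 <= start < end <= length")
  }
  df
}

empty_paf <- function() {
  df <- data.frame(query_id = character(0), query_len = numeric(0),
                   query_start = numeric(0), query_end = numeric(0),
                   strand = character(0), target_id = character(0),
                   target_len = numeric(0), target_start = numeric(0),
                   target_end = numeric(0), matches = numeric(0),
                   block_len = numeric(0), mapq = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Write alignments as PAF
#'
#' Writes the 12 mandatory columns; the inverse of [parse_paf()].
#'
#' @param df alignment data.frame as returned by [parse_paf()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(df, path) {
  if (nrow(df) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  lines <- paste(df$query_id, fmt(df$query_len), fmt(df$query_start),
                 fmt(df$query_end), df$strand, df$target_id,
                 fmt(df$target_len), fmt(df$target_start), fmt(df$target_end),
                 fmt(df$matches), fmt(df$block_len), fmt(df$mapq),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
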