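#' Construct a table of genomic intervals
#'
#' The pipeline's universal coordinate unit: 0-based half-open intervals
#' (BED convention) held in a plain data.frame with columns `chrom`,
#' `start`, `end`, `strand` plus any extra annotation columns.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param strand character vector in `"+"`, `"-"`, `"."`; recycled.
#' @param ... further equal-length annotation columns.
#' @return data.frame with one row per interval.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, non-empty chromosome names, and legal strand
#' codes. Used by every reader and constructor.
#'
#' @param df data.frame with chrom/start/end (strand optional).
#' @param what label used in error messages.
#' @return `df`, invisibly, on success.
#' @export
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s %d violates 0 <= start < end (start=%s, end=%s)",
                 what, bad[1], format(df$start[bad[1]]), format(df$end[bad[1]])))
  }
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) {
    stop(sprintf("%s with empty chromosome name", what))
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stop(sprintf("%s with strand outside {+, -, .}", what))
  }
  invisible(df)
}

# Internal: interval data.frame -> GRanges (0-based half-open -> 1-based closed)
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand
  )
}

# Internal: GRanges -> interval data.frame (back to 0-based half-open)
from_granges <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = ifelse(strand == "*", ".", strand),
    stringsAsFactors = FALSE
  )
}

#' Test half-open overlap between two single intervals
#'
#' Two intervals overlap iff they share a chromosome and
#' `a$start < b$end && b$start < a$end`. Adjacent intervals
#' (`a$end == b$start`) do not overlap. Strand is ignored.
#'
#' @param a,b single-row interval data.frames (or lists with chrom/start/end).
#' @return logical scalar.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Pairs of overlapping intervals between two interval tables
#'
#' Half-open overlap on matching chromosomes; strand ignored. The
#' workhorse behind binding-site selection and anchor-to-node assignment.
#'
#' @param query,subject interval data.frames.
#' @return data.frame with columns `query`, `subject` (row indices) and
#'   `overlap_bp` (width of the intersection).
#' @export
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = numeric()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, overlap_bp = ov)
}

#' Jaccard similarity of two intervals
#'
#' Intersection width over union width on the genomic axis; 0 for
#' intervals on different chromosomes.
#'
#' @param a,b single-row interval data.frames.
#' @return numeric scalar in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  inter <- max(0, min(a$end, b$end) - max(a$start, b$start))
  if (inter == 0) return(0)
  uni <- max(a$end, b$end) - min(a$start, b$start)
  inter / uni
}

# Round half away from zero to `digits` decimals. base::round() rounds
# half-to-even, which breaks printed-percentage reproduction.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
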