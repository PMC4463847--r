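#' Genomic interval helpers
#'
#' All internal coordinates in natscape are 0-based, half-open
#' (`start` inclusive, `end` exclusive), on an explicit strand.  Conversion
#' from the 1-based inclusive convention of GFF3/BED name columns happens
#' only at the I/O boundary (see [read_gff3()] and friends), so interval
#' arithmetic everywhere else is plain `end - start` with no off-by-one
#' corrections.
#'
#' @param chrom chromosome name(s)
#' @param start 0-based inclusive start(s)
#' @param end exclusive end(s); must satisfy `start < end`
#' @param strand one of `"+"`, `"-"`, `"."` (recycled)
#' @return a data.frame with columns `chrom`, `start`, `end`, `strand`
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval start/end must be numeric and non-missing")
  }
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval must have positive length (start < end)")
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad)) stop("unknown strand: ", paste(unique(strand[bad]), collapse = ", "))
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(start)),
             stringsAsFactors = FALSE)
}

#' @rdname genomic_interval
#' @param x an interval data.frame
#' @export
interval_length <- function(x) x$end - x$start

#' 5' and 3' coordinates of stranded intervals
#'
#' For a `-` strand feature the 5' end is the `end` side and the 3' end the
#' `start` side; orientation logic downstream (convergent/divergent calls,
#' metagene binning, promoter placement) goes through these helpers and never
#' touches raw coordinates.
#'
#' @param x interval data.frame with columns `start`, `end`, `strand`
#' @return numeric vector of coordinates (half-open convention: the 5' end of
#'   a `+` feature is `start`, of a `-` feature is `end`)
#' @export
five_prime <- function(x) ifelse(x$strand == "-", x$end, x$start)

#' @rdname five_prime
#' @export
three_prime <- function(x) ifelse(x$strand == "-", x$start, x$end)

# 0-based half-open data.frame -> GRanges (1-based closed) for IRanges ops.
as_granges0 <- function(x, use_strand = TRUE) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (use_strand && !is.null(x$strand)) x$strand else "*")
}

# Overlap length between one interval [s1,e1) and vectors [s2,e2); 0 if none.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
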