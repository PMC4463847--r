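#' Classify the orientation of an opposite-strand gene pair
#'
#' The five cis-NAT subtypes: `containing` (one span nested in the other,
#' including equal spans), `convergent` (tail-to-tail overlap: the 3' ends
#' meet), `divergent` (head-to-head overlap: the 5' ends meet), and the
#' non-overlapping `nearby_head_to_head` / `nearby_tail_to_tail` decided by
#' which ends face each other across the gap.
#'
#' @param a,b single-row interval data.frames (chrom, start, end, strand) on
#'   opposite strands of the same chromosome
#' @return the subtype string
#' @export
classify_orientation <- function(a, b) {
  if (a$strand == b$strand) stop("same-strand input: not an antisense pair")
  if (a$chrom != b$chrom) stop("pair members on different chromosomes")
  plus <- if (a$strand == "+") a else b
  minus <- if (a$strand == "+") b else a
  ov <- overlap_width(plus$start, plus$end, minus$start, minus$end)
  if (ov >= 1) {
    nested <- (plus$start <= minus$start && minus$end <= plus$end) ||
      (minus$start <= plus$start && plus$end <= minus$end)
    if (nested) return("containing")
    # non-nested overlap: the left gene contributes its right (end) side
    if (plus$start < minus$start) {
      # + gene on the left: its 3' end meets the - gene's 3' (start) side
      "convergent"
    } else {
      # - gene on the left: 5' ends meet in the overlap
      "divergent"
    }
  } else {
    if (plus$end <= minus$start) "nearby_tail_to_tail" else "nearby_head_to_head"
  }
}

#' Find and classify cis-NAT pairs
#'
#' Emits every opposite-strand transcript pair that overlaps by at least
#' `min_overlap` nt on the genome, or lies within `nearby_max_gap` nt, once
#' per canonical ordering (lexicographically smaller transcript id first),
#' classified by [classify_orientation()].  Overlap is computed on full
#' transcript spans.  Pairs are then deduplicated to gene level, keeping the
#' pair with the longest overlap per gene pair.
#'
#' @param catalog transcript data.frame as from [read_gff3()]`$transcripts`
#' @param nearby_max_gap maximum gap (nt) for the nearby subtypes; this
#'   cutoff is a pipeline parameter, not a published constant
#' @param min_overlap minimum overlap (nt) for the overlapping subtypes
#' @return data.frame of pairs: pair_id, transcript_a/b, gene_a/b, chrom,
#'   subtype, overlap_start/end (NA for nearby), gap (NA for overlapping),
#'   coding_class (`PC/PC`, `PC/NPC` or `NPC/NPC`), nat_type = "cis"
#' @export
find_cis_pairs <- function(catalog, nearby_max_gap = 100, min_overlap = 1) {
  empty <- data.frame(pair_id = character(), transcript_a = character(),
                      transcript_b = character(), gene_a = character(),
                      gene_b = character(), chrom = character(),
                      subtype = character(), overlap_start = numeric(),
                      overlap_end = numeric(), gap = numeric(),
                      coding_class = character(), nat_type = character(),
                      stringsAsFactors = FALSE)
  if (nrow(catalog) < 2) return(empty)
  gr <- as_granges0(catalog, use_strand = FALSE)
  hits <- GenomicRanges::findOverlaps(gr, maxgap = nearby_max_gap,
                                      drop.self = TRUE, drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  keep <- catalog$strand[i] != catalog$strand[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(empty)

  rows <- lapply(seq_along(i), function(k) {
    a <- catalog[i[k], ]; b <- catalog[j[k], ]
    if (a$transcript_id > b$transcript_id) { tmp <- a; a <- b; b <- tmp }
    ov <- overlap_width(a$start, a$end, b$start, b$end)
    if (ov > 0 && ov < min_overlap) return(NULL)
    subtype <- classify_orientation(a[c("chrom", "start", "end", "strand")],
                                    b[c("chrom", "start", "end", "strand")])
    gap <- if (ov == 0) {
      max(a$start, b$start) - min(a$end, b$end)
    } else NA_real_
    if (!is.na(gap) && (gap < 1 || gap > nearby_max_gap)) return(NULL)
    data.frame(transcript_a = a$transcript_id, transcript_b = b$transcript_id,
               gene_a = a$gene_id, gene_b = b$gene_id, chrom = a$chrom,
               subtype = subtype,
               overlap_start = if (ov > 0) max(a$start, b$start) else NA_real_,
               overlap_end = if (ov > 0) min(a$end, b$end) else NA_real_,
               gap = gap,
               coding_class = pair_coding_class(a$coding_class, b$coding_class),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs) || !nrow(pairs)) return(empty)

  # gene-level dedup: keep the longest overlap per unordered gene pair
  key <- paste(pmin(pairs$gene_a, pairs$gene_b),
               pmax(pairs$gene_a, pairs$gene_b))
  ovlen <- ifelse(is.na(pairs$overlap_start), 0,
                  pairs$overlap_end - pairs$overlap_start)
  pairs <- pairs[order(key, -ovlen), ]
  pairs <- pairs[!duplicated(paste(pmin(pairs$gene_a, pairs$gene_b),
                                   pmax(pairs$gene_a, pairs$gene_b))), ]
  pairs <- pairs[order(pairs$transcript_a, pairs$transcript_b), ]
  pairs <- cbind(pair_id = sprintf("cis%04d", seq_len(nrow(pairs))), pairs,
                 stringsAsFactors = FALSE)
  pairs$nat_type <- "cis"
  rownames(pairs) <- NULL
  pairs
}

pair_coding_class <- function(a, b) {
  n_pc <- (a == "PC") + (b == "PC")
  c("NPC/NPC", "PC/NPC", "PC/PC")[n_pc + 1]
}

#' Position of a cis overlap relative to a protein-coding gene's CDS
#'
#' For each protein-coding member of each overlapping pair, labels where the
#' overlap falls on the transcript: entirely downstream of the CDS
#' (`3'-UTR`), entirely upstream (`5'-UTR`), spanning both CDS boundaries
#' (`across-CDS`), or otherwise intersecting the CDS (`CDS-internal`).
#' Protein-coding members without CDS annotation get `unknown` with a
#' warning.
#'
#' @param pairs cis pair data.frame from [find_cis_pairs()] (overlapping
#'   subtypes only)
#' @param catalog transcript data.frame carrying cds_start/cds_end
#' @return data.frame: pair_id, transcript_id, position
#' @export
classify_overlap_position <- function(pairs, catalog) {
  pairs <- pairs[!is.na(pairs$overlap_start), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    for (id in c(pairs$transcript_a[k], pairs$transcript_b[k])) {
      t <- catalog[match(id, catalog$transcript_id), ]
      if (t$coding_class != "PC") next
      if (is.na(t$cds_start)) {
        warning("protein-coding transcript without CDS annotation: ", id)
        pos <- "unknown"
      } else {
        os <- pairs$overlap_start[k]; oe <- pairs$overlap_end[k]
        # orient genomic sides by strand: upstream = 5' side of the CDS
        if (t$strand == "+") {
          downstream <- os >= t$cds_end
          upstream <- oe <= t$cds_start
        } else {
          downstream <- oe <= t$cds_start
          upstream <- os >= t$cds_end
        }
        spans <- os < t$cds_start && oe > t$cds_end
        pos <- if (downstream) "3'-UTR" else if (upstream) "5'-UTR"
               else if (spans) "across-CDS" else "CDS-internal"
      }
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[k], transcript_id = id, position = pos,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pair_id = character(), transcript_id = character(),
               position = character(), stringsAsFactors = FALSE)
}
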