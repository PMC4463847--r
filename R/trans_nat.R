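#' Search transcript pairs for reverse-complement complementarity
#'
#' For every transcript pair, aligns the first sequence locally against the
#' reverse complement of the second (match/mismatch/affine-gap scoring in
#' DNA space).  A cheap shared-k-mer prefilter skips pairs that cannot reach
#' `min_region`.  Self-pairs and pairs whose genomic loci overlap (cis
#' candidates) are excluded.
#'
#' @param seqs named character vector of transcript sequences
#' @param catalog optional transcript data.frame used to exclude pairs from
#'   overlapping genomic loci
#' @param min_region minimum aligned region length (nt)
#' @param min_identity minimum alignment identity
#' @param k prefilter k-mer size
#' @param min_shared minimum number of shared k-mers required before a pair
#'   is aligned; at the default `k = 13` a real 100 nt duplex at 80%
#'   identity is expected to carry several exact 13-mer matches, while a
#'   chance hit between unrelated transcripts rarely carries more than one
#' @return data.frame of candidates: transcript_a, transcript_b,
#'   a_start/a_end (0-based half-open, coordinates on a), b_start/b_end
#'   (coordinates on b), region_length, identity, aligned_a, aligned_b
#'   (gapped alignment strings, a vs revcomp(b))
#' @export
complementarity_search <- function(seqs, catalog = NULL, min_region = 100,
                                   min_identity = 0.8, k = 13,
                                   min_shared = 2) {
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named by transcript id")
  if (!is.null(catalog)) {
    missing <- setdiff(catalog$transcript_id, ids)
    if (length(missing)) {
      stop("sequence absent for transcript: ", missing[1])
    }
  }
  rc <- stats::setNames(revcomp(seqs), ids)
  kset <- function(s) {
    n <- nchar(s)
    if (n < k) return(stats::setNames(integer(), character()))
    km <- substring(s, 1:(n - k + 1), k:n)
    first <- !duplicated(km)
    stats::setNames(which(first), km[first])
  }
  fwd <- lapply(seqs, kset)
  rck <- lapply(rc, kset)

  # k-mer index: candidate pairs share at least one k-mer between one
  # transcript and the reverse complement of the other
  fk <- unlist(lapply(fwd, names), use.names = FALSE)
  fi <- rep(ids, lengths(fwd))
  rk <- unlist(lapply(rck, names), use.names = FALSE)
  ri <- rep(ids, lengths(rck))
  common <- intersect(fk, rk)
  cand_pairs <- character()
  if (length(common)) {
    fs <- split(fi, factor(fk, levels = common))
    rs <- split(ri, factor(rk, levels = common))
    la <- lengths(fs); lb <- lengths(rs)
    single <- la == 1L & lb == 1L
    g <- data.frame(a = unlist(fs[single], use.names = FALSE),
                    b = unlist(rs[single], use.names = FALSE),
                    stringsAsFactors = FALSE)
    if (any(!single)) {
      pieces <- lapply(which(!single), function(m) {
        expand.grid(a = fs[[m]], b = rs[[m]], stringsAsFactors = FALSE)
      })
      g <- rbind(g, do.call(rbind, pieces))
    }
    g <- g[g$a != g$b, , drop = FALSE]
    if (nrow(g)) {
      # rows are (shared k-mer, ordered pair); count per ordered pair, then
      # canonicalize (counts are symmetric up to reverse complementation)
      cnt <- table(paste(g$a, g$b, sep = "\r"))
      keep <- names(cnt)[cnt >= min_shared]
      if (length(keep)) {
        m <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
        cand_pairs <- unique(paste(pmin(m[, 1], m[, 2]),
                                   pmax(m[, 1], m[, 2]), sep = "\r"))
      }
    }
  }

  cis_excluded <- function(a, b) {
    if (is.null(catalog)) return(FALSE)
    ra <- catalog[match(a, catalog$transcript_id), ]
    rb <- catalog[match(b, catalog$transcript_id), ]
    if (is.na(ra$chrom) || is.na(rb$chrom) || ra$chrom != rb$chrom) return(FALSE)
    overlap_width(ra$start, ra$end, rb$start, rb$end) > 0
  }

  out <- list()
  for (pk in cand_pairs) {
    ab <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    a <- ab[1]; b <- ab[2]
    if (cis_excluded(a, b)) next
    # banded extension: align only a padded window around the shared seeds
    sh <- intersect(names(fwd[[a]]), names(rck[[b]]))
    if (!length(sh)) next
    na <- nchar(seqs[[a]]); nb <- nchar(seqs[[b]])
    pad <- min_region
    ra <- range(fwd[[a]][sh])
    rb <- range(rck[[b]][sh])
    wa <- c(max(1, ra[1] - pad), min(na, ra[2] + k - 1 + pad))
    wb <- c(max(1, rb[1] - pad), min(nb, rb[2] + k - 1 + pad))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(seqs[[a]], wa[1], wa[2])),
      Biostrings::DNAString(substr(rc[[b]], wb[1], wb[2])),
      type = "local", substitutionMatrix = .NAT_SUBMAT,
      gapOpening = 5, gapExtension = 2)
    width_a <- Biostrings::width(Biostrings::pattern(aln))
    if (width_a < min_region) next
    pid <- Biostrings::pid(aln) / 100
    if (pid < min_identity) next
    pa <- Biostrings::pattern(aln); pb <- Biostrings::subject(aln)
    # window -> transcript coordinates; subject is on revcomp(b)
    sa <- Biostrings::start(pa) + wa[1] - 1
    ea <- Biostrings::end(pa) + wa[1] - 1
    sb <- Biostrings::start(pb) + wb[1] - 1
    eb <- Biostrings::end(pb) + wb[1] - 1
    out[[length(out) + 1L]] <- data.frame(
      transcript_a = a, transcript_b = b,
      a_start = sa - 1, a_end = ea,
      b_start = nb - eb, b_end = nb - sb + 1,
      region_length = width_a, identity = pid,
      aligned_a = as.character(Biostrings::alignedPattern(aln)),
      aligned_b = as.character(Biostrings::alignedSubject(aln)),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(transcript_a = character(), transcript_b = character(),
               a_start = numeric(), a_end = numeric(), b_start = numeric(),
               b_end = numeric(), region_length = numeric(),
               identity = numeric(), aligned_a = character(),
               aligned_b = character(), stringsAsFactors = FALSE)
}

.NAT_SUBMAT <- local({
  m <- matrix(-2, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 1
  m["N", ] <- m[, "N"] <- 0
  m
})

#' Verify an antisense duplex with the bubble rule
#'
#' Base-pairs the aligned regions position by position (Watson-Crick in DNA
#' space; optional G:U wobble) and measures every maximal run of unpaired
#' positions ("bubbles": mismatches or gaps on either strand).  The duplex
#' is accepted iff its longest bubble is no longer than `bubble_frac` of
#' the pairing region (inclusive boundary).  The region is measured in
#' alignment columns, so the verdict does not depend on which transcript
#' is called first.
#'
#' @param candidate single-row data.frame from [complementarity_search()]
#' @param bubble_frac maximum bubble length as a fraction of the region
#' @param wobble allow G:U wobble pairs
#' @return the candidate row with added `paired_fraction`, `max_bubble`,
#'   `n_bubbles`, `accepted`
#' @export
verify_duplex <- function(candidate, bubble_frac = 0.10, wobble = FALSE) {
  stopifnot(nrow(candidate) == 1)
  a <- strsplit(candidate$aligned_a, "")[[1]]
  b <- strsplit(candidate$aligned_b, "")[[1]]
  if (!length(a)) stop("zero-length pairing region")
  paired <- a == b & a != "-"
  if (wobble) {
    # in (a, revcomp(b)) space, G:U duplex pairs appear as G~A and T~C
    paired <- paired | (a == "G" & b == "A") | (a == "T" & b == "C")
  }
  runs <- rle(paired)
  bubbles <- runs$lengths[!runs$values]
  region_length <- length(a)  # alignment columns: orientation-symmetric
  candidate$region_length <- region_length
  candidate$paired_fraction <- mean(paired)
  candidate$max_bubble <- if (length(bubbles)) max(bubbles) else 0L
  candidate$n_bubbles <- length(bubbles)
  candidate$accepted <- candidate$max_bubble <= bubble_frac * region_length
  candidate
}

#' Identify trans-NAT pairs
#'
#' Runs [complementarity_search()] and [verify_duplex()] over a transcript
#' catalog, keeping accepted duplexes, and projects the transcript-coordinate
#' pairing regions to genomic coordinates (contiguous single-exon
#' transcripts).
#'
#' @inheritParams complementarity_search
#' @inheritParams verify_duplex
#' @param catalog transcript data.frame (required here, for coding classes
#'   and genomic projection)
#' @return data.frame of accepted pairs with pairing-region coordinates in
#'   transcript and genomic space, paired_fraction, max_bubble,
#'   coding_class and nat_type = "trans"
#' @export
find_trans_pairs <- function(seqs, catalog, min_region = 100,
                             min_identity = 0.8, bubble_frac = 0.10,
                             wobble = FALSE, k = 13, min_shared = 2) {
  cand <- complementarity_search(seqs, catalog, min_region = min_region,
                                 min_identity = min_identity, k = k,
                                 min_shared = min_shared)
  if (!nrow(cand)) return(cbind(cand[0, ], accepted = logical()))
  verified <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    verify_duplex(cand[i, ], bubble_frac = bubble_frac, wobble = wobble)
  }))
  acc <- verified[verified$accepted, , drop = FALSE]
  if (!nrow(acc)) {
    acc$pair_id <- character()
    acc$nat_type <- character()
    return(acc)
  }
  proj <- function(id, t_start, t_end) {
    t <- catalog[match(id, catalog$transcript_id), ]
    if (t$strand == "+") c(t$start + t_start, t$start + t_end)
    else c(t$end - t_end, t$end - t_start)
  }
  g <- t(vapply(seq_len(nrow(acc)), function(i) {
    c(proj(acc$transcript_a[i], acc$a_start[i], acc$a_end[i]),
      proj(acc$transcript_b[i], acc$b_start[i], acc$b_end[i]))
  }, numeric(4)))
  acc$region_a_gstart <- g[, 1]; acc$region_a_gend <- g[, 2]
  acc$region_b_gstart <- g[, 3]; acc$region_b_gend <- g[, 4]
  cca <- catalog$coding_class[match(acc$transcript_a, catalog$transcript_id)]
  ccb <- catalog$coding_class[match(acc$transcript_b, catalog$transcript_id)]
  acc$coding_class <- mapply(pair_coding_class, cca, ccb)
  acc$gene_a <- catalog$gene_id[match(acc$transcript_a, catalog$transcript_id)]
  acc$gene_b <- catalog$gene_id[match(acc$transcript_b, catalog$transcript_id)]
  acc$chrom_a <- catalog$chrom[match(acc$transcript_a, catalog$transcript_id)]
  acc$chrom_b <- catalog$chrom[match(acc$transcript_b, catalog$transcript_id)]
  acc$pair_id <- sprintf("trans%04d", seq_len(nrow(acc)))
  acc$nat_type <- "trans"
  rownames(acc) <- NULL
  acc
}
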