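#' Longest open reading frame, in amino acids
#'
#' Scans the three forward reading frames for the longest ATG-initiated,
#' stop-terminated ORF and reports its length in amino acids, excluding the
#' stop codon.  Candidates are stranded transcripts, so reverse frames are
#' not scanned unless requested.
#'
#' @param sequence nucleotide string over A/C/G/T/N
#' @param both_strands also scan the reverse complement
#' @return amino-acid length of the longest ORF (0 if none)
#' @export
longest_orf_aa <- function(sequence, both_strands = FALSE) {
  if (!nzchar(sequence)) stop("empty sequence")
  best <- .orf_scan(toupper(sequence))
  if (both_strands) best <- max(best, .orf_scan(revcomp(toupper(sequence))))
  best
}

.orf_scan <- function(s) {
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq(frame + 1, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- substring(s, starts, starts + 2)
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        best <- max(best, i - open_at)
        open_at <- NA_integer_
      }
    }
  }
  best
}

#' Filter lncRNA candidates
#'
#' Applies the standard plant lncRNA retention rules: an intergenic,
#' antisense or intronic assembly (class code u/x/i) is kept iff it is
#' longer than `min_len` nucleotides (strict), its longest ORF is at most
#' `max_orf` amino acids, its coding probability is below
#' `max_coding_prob`, it is not homologous to an annotated transcript, and
#' its FPKM is at least `min_fpkm` in every sample where it was assembled
#' (a transcript with FPKM below the floor in any such sample is removed).
#'
#' @param candidates data.frame with columns transcript_id, class_code,
#'   length, max_orf_aa, coding_prob, homologous_to_annotation, and either a
#'   list-column `fpkm` (named numeric per sample) or numeric columns
#'   prefixed `fpkm_`
#' @param min_len,max_orf,max_coding_prob,min_fpkm thresholds; defaults are
#'   the published cutoffs (200 nt, 120 aa, 0.365, FPKM 2)
#' @return the input with added logical `retained` and character
#'   `reject_reason` (NA when retained)
#' @export
filter_lncrna <- function(candidates, min_len = 200, max_orf = 120,
                          max_coding_prob = 0.365, min_fpkm = 2) {
  fpkm_cols <- grep("^fpkm", names(candidates), value = TRUE)
  if (!length(fpkm_cols)) stop("candidates must carry fpkm values")
  reason <- rep(NA_character_, nrow(candidates))
  flag <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  flag(!candidates$class_code %in% c("u", "x", "i"), "class_code")
  flag(!(candidates$length > min_len), "length")
  flag(!(candidates$max_orf_aa <= max_orf), "orf")
  flag(!(candidates$coding_prob < max_coding_prob), "coding_prob")
  flag(candidates$homologous_to_annotation, "homology")
  if (identical(fpkm_cols, "fpkm") && is.list(candidates$fpkm)) {
    low <- vapply(candidates$fpkm, function(v) {
      v <- v[!is.na(v)]
      length(v) > 0 && any(v < min_fpkm)
    }, logical(1))
  } else {
    m <- as.matrix(candidates[fpkm_cols])
    low <- apply(m, 1, function(v) any(v[!is.na(v)] < min_fpkm))
  }
  flag(low, "fpkm")
  candidates$retained <- is.na(reason)
  candidates$reject_reason <- reason
  candidates
}
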