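#' Join enriched tiles into domains
#'
#' Neighbouring enriched tiles of the same mark on the same chromosome are
#' merged when the edge-to-edge gap between them is at most `max_gap` nt
#' (inclusive); merged intervals shorter than `min_domain` nt are
#' discarded.  Output is independent of input tile order, and running the
#' function on its own output is the identity.
#'
#' @param tiles data.frame chrom/start/end/mark
#' @param max_gap maximal joined gap (nt), boundary inclusive
#' @param min_domain minimal retained domain length (nt), boundary inclusive
#' @return data.frame chrom/start/end/mark of domains
#' @export
tiles_to_domains <- function(tiles, max_gap = 200, min_domain = 400) {
  out <- list()
  for (key in unique(paste(tiles$chrom, tiles$mark, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    t <- tiles[tiles$chrom == parts[1] & tiles$mark == parts[2], , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(t$start + 1, t$end),
                          min.gapwidth = max_gap + 1)
    ir <- ir[IRanges::width(ir) >= min_domain]
    if (!length(ir)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = parts[1], start = IRanges::start(ir) - 1,
      end = as.numeric(IRanges::end(ir)), mark = parts[2],
      stringsAsFactors = FALSE)
  }
  if (length(out)) {
    d <- do.call(rbind, out)
    d <- d[order(d$chrom, d$mark, d$start), ]
    rownames(d) <- NULL
    d
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mark = character(), stringsAsFactors = FALSE)
  }
}

#' Chromatin group state of genes
#'
#' A mark targets a gene iff one of its domains overlaps the gene span by
#' at least one nt.  Genes targeted only by euchromatic marks (H3K4me2,
#' H3K4me3, H3K36me3, H2Bub) are `G1`; only by heterochromatic marks
#' (H3K27me1, H3K27me3) are `G2`; by both groups `G1+G2`; by neither
#' `NON`.
#'
#' @param catalog transcript data.frame
#' @param domains data.frame from [tiles_to_domains()]
#' @return data.frame transcript_id/gene_id/marks_present/group_state
#' @export
gene_mark_state <- function(catalog, domains) {
  known <- c(G1_MARKS, G2_MARKS)
  bad <- setdiff(unique(domains$mark), known)
  if (length(bad)) stop("unknown mark name: ", paste(bad, collapse = ", "))
  state <- character(nrow(catalog))
  marks <- character(nrow(catalog))
  if (nrow(domains)) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(catalog, use_strand = FALSE),
      as_granges0(domains, use_strand = FALSE))
    by_gene <- split(domains$mark[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
  } else {
    by_gene <- list()
  }
  for (i in seq_len(nrow(catalog))) {
    m <- unique(by_gene[[as.character(i)]])
    has_g1 <- any(m %in% G1_MARKS); has_g2 <- any(m %in% G2_MARKS)
    state[i] <- if (has_g1 && has_g2) "G1+G2" else if (has_g1) "G1"
                else if (has_g2) "G2" else "NON"
    marks[i] <- paste(sort(m), collapse = ",")
  }
  data.frame(transcript_id = catalog$transcript_id,
             gene_id = catalog$gene_id, marks_present = marks,
             group_state = state, stringsAsFactors = FALSE)
}

#' Metagene enrichment profile
#'
#' Per gene: 100 upstream bins of `flank_bin` bp, `body_bins` bins each
#' covering 1/`body_bins` of the gene length, and 100 downstream bins,
#' strand-flipped so bin 1 is always the 5' end.  The signal is domain
#' membership (per-position 0/1, averaged within each bin), and profiles
#' are averaged over the gene set.  Genes shorter than `body_bins` nt are
#' skipped with a warning.
#'
#' @param genes transcript data.frame
#' @param domains data.frame for a single mark (chrom/start/end)
#' @param body_bins number of body bins
#' @param flank flank extent (nt)
#' @param flank_bin flank bin width (nt)
#' @return numeric vector of length `flank/flank_bin + body_bins +
#'   flank/flank_bin`: the mean profile, 5' flank first
#' @export
metagene_profile <- function(genes, domains, body_bins = 100, flank = 1000,
                             flank_bin = 10) {
  n_flank <- flank / flank_bin
  short <- interval_length(genes) < body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than body_bins nt skipped")
    genes <- genes[!short, , drop = FALSE]
  }
  acc <- matrix(0, nrow = nrow(genes), ncol = 2 * n_flank + body_bins)
  bin_means <- function(chrom, edges) {
    d <- domains[domains$chrom == chrom, , drop = FALSE]
    s <- edges[-length(edges)]; e <- edges[-1]
    vapply(seq_along(s), function(b) {
      if (e[b] <= s[b]) return(NA_real_)
      sum(overlap_width(s[b], e[b], d$start, d$end)) / (e[b] - s[b])
    }, numeric(1))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    up_edges <- seq(g$start - flank, g$start, by = flank_bin)
    body_edges <- g$start + (g$end - g$start) * (0:body_bins) / body_bins
    down_edges <- seq(g$end, g$end + flank, by = flank_bin)
    prof <- c(bin_means(g$chrom, up_edges), bin_means(g$chrom, body_edges),
              bin_means(g$chrom, down_edges))
    if (g$strand == "-") prof <- rev(prof)
    acc[i, ] <- prof
  }
  colMeans(acc, na.rm = TRUE)
}

# precedence used to name unordered pair-pattern classes
.STATE_ORDER <- c("G1+G2", "G1", "G2", "NON")

PAIR_PATTERN_CLASSES <- c("G1_G1", "G2_G2", "G1_G2", "G1+G2_G1", "G1+G2_G2",
                          "G1+G2_G1+G2", "G1+G2_NON", "G1_NON", "G2_NON",
                          "NON_NON")

pair_pattern_class <- function(state_a, state_b) {
  ra <- match(state_a, .STATE_ORDER); rb <- match(state_b, .STATE_ORDER)
  first <- ifelse(ra <= rb, state_a, state_b)
  second <- ifelse(ra <= rb, state_b, state_a)
  cls <- paste(first, second, sep = "_")
  # canonical names list G1_G2 with G1 first
  cls[cls == "G2_G1"] <- "G1_G2"
  cls
}

#' Classify NAT pairs into the ten modification pattern classes
#'
#' Each pair is assigned the unordered combination of its two genes' group
#' states; the 16 ordered combinations collapse to 10 unordered classes.
#' Pairs with a member lacking a state are dropped and counted.
#'
#' @param pairs pair data.frame with transcript_a/transcript_b
#' @param states data.frame from [gene_mark_state()] (or any table with
#'   transcript_id and group_state)
#' @return list: `per_pair` (pair_id, class), `percentages` (named vector
#'   over the 10 classes, summing to 100), `n_pairs`, `n_dropped`
#' @export
classify_pair_patterns <- function(pairs, states) {
  sa <- states$group_state[match(pairs$transcript_a, states$transcript_id)]
  sb <- states$group_state[match(pairs$transcript_b, states$transcript_id)]
  ok <- !is.na(sa) & !is.na(sb)
  cls <- pair_pattern_class(sa[ok], sb[ok])
  counts <- table(factor(cls, levels = PAIR_PATTERN_CLASSES))
  list(per_pair = data.frame(pair_id = pairs$pair_id[ok], class = cls,
                             stringsAsFactors = FALSE),
       percentages = stats::setNames(
         100 * as.vector(counts) / max(sum(ok), 1), PAIR_PATTERN_CLASSES),
       n_pairs = sum(ok), n_dropped = sum(!ok))
}

#' Randomized non-NAT pair-pattern null
#'
#' Each repeat draws `n_pairs` gene pairs from the non-NAT pool (two sets
#' matched in number to the observed group, paired randomly, without
#' replacement within a repeat), classifies them, and records the per-class
#' percentages.  Returns the mean and a 2.5/97.5 percentile envelope over
#' repeats.  Deterministic given `seed`.
#'
#' @param pool_states character vector of group states for the non-NAT pool
#' @param n_pairs number of pairs per repeat
#' @param repeats number of repeats
#' @param seed RNG seed
#' @return list: `mean`, `lower`, `upper` (named percentage vectors over
#'   the 10 classes), `repeats`
#' @export
randomized_null <- function(pool_states, n_pairs, repeats = 10000,
                            seed = 1) {
  if (length(pool_states) < 2 * n_pairs) {
    stop("non-NAT pool smaller than 2 * n_pairs")
  }
  set.seed(seed)
  codes <- match(pool_states, .STATE_ORDER)
  class_lookup <- outer(.STATE_ORDER, .STATE_ORDER, pair_pattern_class)
  class_idx <- matrix(match(class_lookup, PAIR_PATTERN_CLASSES), 4, 4)
  pct <- matrix(0, nrow = repeats, ncol = length(PAIR_PATTERN_CLASSES))
  n <- length(codes)
  for (r in seq_len(repeats)) {
    idx <- sample.int(n, 2 * n_pairs)
    a <- codes[idx[seq_len(n_pairs)]]
    b <- codes[idx[n_pairs + seq_len(n_pairs)]]
    tab <- tabulate(class_idx[cbind(a, b)], nbins = length(PAIR_PATTERN_CLASSES))
    pct[r, ] <- 100 * tab / n_pairs
  }
  colnames(pct) <- PAIR_PATTERN_CLASSES
  list(mean = colMeans(pct),
       lower = apply(pct, 2, stats::quantile, 0.025),
       upper = apply(pct, 2, stats::quantile, 0.975),
       repeats = repeats)
}
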