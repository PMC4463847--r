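#' Per-pair small-RNA densities in overlap vs non-overlap regions
#'
#' For one NAT pair and one data set: `density_o` is the number of distinct
#' small-RNA loci fully contained in the pair's overlap/pairing region(s)
#' divided by their total length, and `density_g` is the count in the union
#' of the two gene spans minus those regions, divided by that length
#' (shared nucleotides counted once).
#'
#' @param pair single-row pair data.frame (cis or trans)
#' @param library filtered read data.frame, restricted by `dataset`
#' @param catalog transcript data.frame
#' @param dataset data set id (NULL = all rows of `library`)
#' @param count_mode `"loci"` (distinct loci, default) or `"reads"`
#'   (sum of read counts)
#' @return list: density_o, density_g, N_o, L_o, N_g, L_g, usable (FALSE
#'   when the non-overlap length is zero)
#' @export
pair_densities <- function(pair, library, catalog, dataset = NULL,
                           count_mode = c("loci", "reads")) {
  count_mode <- match.arg(count_mode)
  stopifnot(nrow(pair) == 1)
  regions <- pair_overlap_regions(pair)
  regions <- unique(regions[c("chrom", "start", "end")])
  if (!nrow(regions)) stop("pair has no overlap region")
  L_o <- sum(regions$end - regions$start)
  if (L_o == 0) stop("pair has no overlap region")

  members <- catalog[match(c(pair$transcript_a, pair$transcript_b),
                           catalog$transcript_id), ]
  span_gr <- GenomicRanges::reduce(as_granges0(members, use_strand = FALSE))
  ov_gr <- as_granges0(cbind(regions, strand = "."), use_strand = FALSE)
  gene_gr <- GenomicRanges::setdiff(span_gr, ov_gr)
  L_g <- sum(GenomicRanges::width(gene_gr))

  if (!is.null(dataset)) {
    library <- library[library$dataset_id == dataset, , drop = FALSE]
  }
  loci <- unique(library[c("sequence", "chrom", "start", "end")])
  counts <- if (count_mode == "reads") {
    key <- paste(library$sequence, library$chrom, library$start, library$end)
    lkey <- paste(loci$sequence, loci$chrom, loci$start, loci$end)
    as.numeric(tapply(library$count, key, sum)[lkey])
  } else rep(1, nrow(loci))

  contained <- function(gr) {
    if (!nrow(loci)) return(0)
    lg <- as_granges0(loci, use_strand = FALSE)
    hits <- GenomicRanges::findOverlaps(lg, gr, type = "within")
    sum(counts[unique(S4Vectors::queryHits(hits))])
  }
  N_o <- contained(ov_gr)
  N_g <- contained(gene_gr)
  list(density_o = N_o / L_o,
       density_g = if (L_g > 0) N_g / L_g else NA_real_,
       N_o = N_o, L_o = L_o, N_g = N_g, L_g = L_g, usable = L_g > 0)
}

#' Overlap-region enrichment score and one-tailed paired t-test
#'
#' For each pair in the stratum, computes overlap and non-overlap densities
#' ([pair_densities()]); `A_o` and `A_g` are their means over pairs, the
#' enrichment score is `R = A_o / A_g`, and significance comes from a
#' paired two-sample t-test across pairs, one-tailed in the enrichment
#' direction (overlap density greater than non-overlap density), with
#' `n_pairs - 1` degrees of freedom.
#'
#' @param pairs pair data.frame (one stratum)
#' @param library filtered read data.frame
#' @param catalog transcript data.frame
#' @param dataset data set id (NULL = all)
#' @param stratum label copied to the output
#' @inheritParams pair_densities
#' @return one-row data.frame: dataset_id, stratum, n_pairs, A_o, A_g, R,
#'   t_stat, p_value
#' @export
enrichment_test <- function(pairs, library, catalog, dataset = NULL,
                            stratum = "all", count_mode = "loci") {
  dens <- lapply(seq_len(nrow(pairs)), function(k) {
    pair_densities(pairs[k, ], library, catalog, dataset, count_mode)
  })
  usable <- vapply(dens, `[[`, logical(1), "usable")
  dens <- dens[usable]
  if (length(dens) < 2) stop("insufficient pairs in stratum (need >= 2 usable)")
  d_o <- vapply(dens, `[[`, numeric(1), "density_o")
  d_g <- vapply(dens, `[[`, numeric(1), "density_g")
  A_o <- mean(d_o); A_g <- mean(d_g)
  tt <- paired_t_greater(d_o, d_g)
  t_stat <- tt$t; p <- tt$p
  data.frame(dataset_id = if (is.null(dataset)) "all" else dataset,
             stratum = stratum, n_pairs = length(dens), A_o = A_o, A_g = A_g,
             R = if (A_g > 0) A_o / A_g else NA_real_,
             t_stat = t_stat, p_value = p, stringsAsFactors = FALSE)
}

# one-tailed paired t (H1: x > y), df = n - 1; degenerate differences give
# the null midpoint rather than NA so all-zero data sets stay usable
paired_t_greater <- function(x, y) {
  d <- x - y
  if (stats::sd(d) == 0) return(list(t = 0, p = 0.5))
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Calibration of the overlap-enrichment test
#'
#' Simulates data sets under the same sampling scheme the synthetic
#' generator uses for small-RNA loci — per pair, an overlap region and a
#' non-overlap gene region with Poisson locus counts at the given per-nt
#' rates — and returns the one-tailed paired-t p-value of each simulated
#' data set.  With equal rates this measures the test's type-I error; with
#' `rate_overlap > rate_background` its power.
#'
#' @param n_sims number of simulated data sets
#' @param n_pairs pairs per data set
#' @param rate_overlap,rate_background expected loci per nt
#' @param overlap_length,gene_length sampling ranges (nt) for the overlap
#'   region and the total non-overlap gene length
#' @param seed RNG seed
#' @return numeric vector of `n_sims` p-values
#' @export
enrichment_calibration <- function(n_sims, n_pairs, rate_overlap,
                                   rate_background,
                                   overlap_length = c(100, 300),
                                   gene_length = c(1500, 3500), seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_sims), function(s) {
    L_o <- runif_int(n_pairs, overlap_length)
    L_g <- runif_int(n_pairs, gene_length)
    d_o <- stats::rpois(n_pairs, rate_overlap * L_o) / L_o
    d_g <- stats::rpois(n_pairs, rate_background * L_g) / L_g
    paired_t_greater(d_o, d_g)$p
  }, numeric(1))
}

#' Enrichment table across data sets and strata
#'
#' Rows are data sets, strata are the cis/trans x coding-class groups:
#' all NATs, all cis, cis PC/PC, cis PC/NPC, cis NPC/NPC, all trans, and
#' the trans coding-class groups.  Strata with fewer than two usable pairs
#' are reported with NA statistics.
#'
#' @inheritParams enrichment_test
#' @param datasets character vector of data set ids
#' @return long data.frame of [enrichment_test()] rows
#' @export
enrichment_table <- function(pairs, library, catalog, datasets,
                             count_mode = "loci") {
  cis <- pairs[pairs$nat_type == "cis" & !is.na(pairs$overlap_start), ,
               drop = FALSE]
  tr <- pairs[pairs$nat_type == "trans", , drop = FALSE]
  strata <- list(all_nats = rbind_pairs(cis, tr), all_cis = cis,
                 cis_pc_pc = cis[cis$coding_class == "PC/PC", ],
                 cis_pc_npc = cis[cis$coding_class == "PC/NPC", ],
                 cis_npc_npc = cis[cis$coding_class == "NPC/NPC", ],
                 all_trans = tr,
                 trans_pc_pc = tr[tr$coding_class == "PC/PC", ],
                 trans_pc_npc = tr[tr$coding_class == "PC/NPC", ],
                 trans_npc_npc = tr[tr$coding_class == "NPC/NPC", ])
  out <- list()
  for (d in datasets) {
    for (s in names(strata)) {
      res <- tryCatch(
        enrichment_test(strata[[s]], library, catalog, d, s, count_mode),
        error = function(e) data.frame(
          dataset_id = d, stratum = s, n_pairs = nrow(strata[[s]]),
          A_o = NA_real_, A_g = NA_real_, R = NA_real_, t_stat = NA_real_,
          p_value = NA_real_, stringsAsFactors = FALSE))
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

# bind cis and trans pair tables on their shared columns
rbind_pairs <- function(cis, tr) {
  shared <- c("pair_id", "transcript_a", "transcript_b", "coding_class",
              "nat_type")
  extra_cis <- c("chrom", "overlap_start", "overlap_end")
  extra_tr <- c("chrom_a", "chrom_b", "region_a_gstart", "region_a_gend",
                "region_b_gstart", "region_b_gend")
  pad <- function(df, cols) {
    for (cc in cols) if (!cc %in% names(df)) df[[cc]] <- rep(NA, nrow(df))
    df[c(shared, extra_cis, extra_tr)]
  }
  rbind(pad(cis, c(extra_cis, extra_tr)), pad(tr, c(extra_cis, extra_tr)))
}

#' dsRNA coverage check: overlap region vs flanks
#'
#' Per pair, compares mean read coverage (aligned bases per nt) in the
#' overlap region against its flanks (each flank as long as the overlap,
#' truncated at the outer gene boundaries), and aggregates with a
#' one-tailed paired t-test across pairs (overlap > flanks).
#'
#' @param pairs cis pair data.frame (overlapping subtypes)
#' @param coverage_reads data.frame chrom/start/end of dsRNA-supporting
#'   read intervals
#' @param catalog transcript data.frame
#' @return list: `per_pair` data.frame (pair_id, cov_overlap, cov_flank,
#'   ratio) and `p_value`
#' @export
dsrna_overlap_check <- function(pairs, coverage_reads, catalog) {
  mean_cov <- function(chrom, s, e) {
    if (e <= s) return(NA_real_)
    r <- coverage_reads[coverage_reads$chrom == chrom, , drop = FALSE]
    sum(overlap_width(s, e, r$start, r$end)) / (e - s)
  }
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    if (is.na(p$overlap_start)) next
    members <- catalog[match(c(p$transcript_a, p$transcript_b),
                             catalog$transcript_id), ]
    lo <- p$overlap_end - p$overlap_start
    left_s <- max(min(members$start), p$overlap_start - lo)
    right_e <- min(max(members$end), p$overlap_end + lo)
    fl <- c(mean_cov(p$chrom, left_s, p$overlap_start),
            mean_cov(p$chrom, p$overlap_end, right_e))
    fl <- fl[!is.na(fl)]
    if (!length(fl)) next
    co <- mean_cov(p$chrom, p$overlap_start, p$overlap_end)
    cf <- mean(fl)
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = p$pair_id, cov_overlap = co, cov_flank = cf,
      ratio = if (cf > 0) co / cf else NA_real_, stringsAsFactors = FALSE)
  }
  per_pair <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), cov_overlap = numeric(),
               cov_flank = numeric(), ratio = numeric(),
               stringsAsFactors = FALSE)
  p_value <- if (nrow(per_pair) >= 2 &&
                 stats::sd(per_pair$cov_overlap - per_pair$cov_flank) > 0) {
    stats::t.test(per_pair$cov_overlap, per_pair$cov_flank, paired = TRUE,
                  alternative = "greater")$p.value
  } else NA_real_
  list(per_pair = per_pair, p_value = p_value)
}
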