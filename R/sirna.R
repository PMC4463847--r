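#' Build the filtered small-RNA library
#'
#' Retains reads that (i) do not overlap any excluded ncRNA locus (rRNA,
#' snRNA, snoRNA, miRNA — tRNA loci are deliberately preserved and are
#' dropped from the exclusion set if present), (ii) map to exactly one
#' genomic locus, and (iii) are between `min_len` and `max_len` nt.
#'
#' @param reads hit data.frame as from [read_smrna_table()] (one row per
#'   hit; multi-mappers have several rows per read id within a data set)
#' @param exclusion data.frame chrom/start/end/mark of ncRNA loci (`mark` is
#'   the ncRNA class); may be NULL
#' @param min_len,max_len read length bounds (nt)
#' @return list: `library` (one row per retained read) and `rejected`
#'   (named counts per filter)
#' @export
build_library <- function(reads, exclusion = NULL, min_len = 18, max_len = 28) {
  rejected <- c(excluded_class = 0L, multi_mapper = 0L, length = 0L)
  if (!is.null(exclusion) && "mark" %in% names(exclusion)) {
    exclusion <- exclusion[exclusion$mark != "tRNA", , drop = FALSE]
  }
  if (!is.null(exclusion) && nrow(exclusion) && nrow(reads)) {
    hit_gr <- as_granges0(reads, use_strand = FALSE)
    ex_gr <- as_granges0(exclusion, use_strand = FALSE)
    bad_hits <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(hit_gr, ex_gr)))
    bad_reads <- unique(paste(reads$dataset_id, reads$read_id)[bad_hits])
    drop <- paste(reads$dataset_id, reads$read_id) %in% bad_reads
    rejected["excluded_class"] <- length(bad_reads)
    reads <- reads[!drop, , drop = FALSE]
  }
  if (nrow(reads)) {
    key <- paste(reads$dataset_id, reads$read_id)
    nhits <- table(key)
    multi <- names(nhits)[nhits > 1]
    rejected["multi_mapper"] <- length(multi)
    reads <- reads[!key %in% multi, , drop = FALSE]
  }
  if (nrow(reads)) {
    bad_len <- reads$length < min_len | reads$length > max_len
    rejected["length"] <- sum(bad_len)
    reads <- reads[!bad_len, , drop = FALSE]
  }
  rownames(reads) <- NULL
  list(library = reads, rejected = rejected)
}

# one row per dsRNA-forming region of each pair (cis overlap, or the two
# pairing-region projections of a trans pair)
pair_overlap_regions <- function(pairs) {
  cis <- pairs[pairs$nat_type == "cis" & !is.na(pairs$overlap_start), ,
               drop = FALSE]
  tr <- pairs[pairs$nat_type == "trans", , drop = FALSE]
  out <- rbind(
    if (nrow(cis)) data.frame(pair_id = cis$pair_id, chrom = cis$chrom,
                              start = cis$overlap_start,
                              end = cis$overlap_end,
                              member = cis$transcript_a,
                              stringsAsFactors = FALSE),
    if (nrow(cis)) data.frame(pair_id = cis$pair_id, chrom = cis$chrom,
                              start = cis$overlap_start,
                              end = cis$overlap_end,
                              member = cis$transcript_b,
                              stringsAsFactors = FALSE),
    if (nrow(tr)) data.frame(pair_id = tr$pair_id, chrom = tr$chrom_a,
                             start = tr$region_a_gstart,
                             end = tr$region_a_gend,
                             member = tr$transcript_a,
                             stringsAsFactors = FALSE),
    if (nrow(tr)) data.frame(pair_id = tr$pair_id, chrom = tr$chrom_b,
                             start = tr$region_b_gstart,
                             end = tr$region_b_gend,
                             member = tr$transcript_b,
                             stringsAsFactors = FALSE))
  if (is.null(out)) data.frame(pair_id = character(), chrom = character(),
                               start = numeric(), end = numeric(),
                               member = character(), stringsAsFactors = FALSE)
  else out
}

#' Call NAT-siRNAs
#'
#' A distinct small-RNA sequence from the filtered library is called a
#' NAT-siRNA iff its (unique) genomic locus lies fully inside the
#' overlap/pairing region of at least one NAT pair and the sequence is
#' observed in at least `min_datasets` data sets.  The producing transcript
#' of each source pair is the member whose strand matches the read; a
#' sequence whose locus belongs to several pairs' regions is flagged
#' `nonunique`.
#'
#' @param library filtered read data.frame from [build_library()]
#' @param pairs combined NAT pair table (cis rows from [find_cis_pairs()],
#'   trans rows from [find_trans_pairs()])
#' @param catalog transcript data.frame (strand and coding class lookup)
#' @param datasets optional data.frame dataset_id/tissue; unknown data sets
#'   get tissue "other" with a warning
#' @param min_datasets reproducibility threshold
#' @return data.frame, one row per called siRNA: sequence, length, chrom,
#'   start, end, strand, datasets_present, n_datasets, tissues_present,
#'   source_pairs, n_source_pairs, uniqueness, producing_transcript,
#'   directional_subtype (producing transcript's class first), nat_type
#' @export
call_nat_sirnas <- function(library, pairs, catalog, datasets = NULL,
                            min_datasets = 3) {
  regions <- pair_overlap_regions(pairs)
  empty <- data.frame(sequence = character(), length = integer(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), datasets_present = character(),
                      n_datasets = integer(), tissues_present = character(),
                      source_pairs = character(), n_source_pairs = integer(),
                      uniqueness = character(),
                      producing_transcript = character(),
                      directional_subtype = character(), nat_type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(library) || !nrow(regions)) return(empty)

  # distinct sequences; unique mapping guarantees one locus per sequence
  seq_split <- split(library, library$sequence)
  gene_pairs <- table(c(pairs$transcript_a, pairs$transcript_b))

  tissue_of <- function(ds) {
    if (is.null(datasets)) return(rep("other", length(ds)))
    t <- datasets$tissue[match(ds, datasets$dataset_id)]
    if (any(is.na(t))) {
      warning("data set(s) without tissue metadata: ",
              paste(ds[is.na(t)], collapse = ", "))
      t[is.na(t)] <- "other"
    }
    t
  }

  out <- list()
  for (s in names(seq_split)) {
    rows <- seq_split[[s]]
    ds <- unique(rows$dataset_id)
    if (length(ds) < min_datasets) next
    locus <- rows[1, c("chrom", "start", "end", "strand")]
    inside <- regions$chrom == locus$chrom &
      regions$start <= locus$start & locus$end <= regions$end
    if (!any(inside)) next
    src <- regions[inside, , drop = FALSE]
    src_pairs <- unique(src$pair_id)

    # producing transcript: region member whose strand matches the read
    strands <- catalog$strand[match(src$member, catalog$transcript_id)]
    same <- src$member[strands == locus$strand]
    producing <- if (length(same)) same[1] else src$member[1]
    prod_class <- catalog$coding_class[match(producing, catalog$transcript_id)]
    partner_pair <- pairs[match(src$pair_id[match(producing, src$member)],
                                pairs$pair_id), ]
    partner <- if (partner_pair$transcript_a == producing) {
      partner_pair$transcript_b
    } else partner_pair$transcript_a
    partner_class <- catalog$coding_class[match(partner, catalog$transcript_id)]

    out[[length(out) + 1L]] <- data.frame(
      sequence = s, length = rows$length[1], chrom = locus$chrom,
      start = locus$start, end = locus$end, strand = locus$strand,
      datasets_present = paste(sort(ds), collapse = ","),
      n_datasets = length(ds),
      tissues_present = paste(sort(unique(tissue_of(ds))), collapse = ","),
      source_pairs = paste(sort(src_pairs), collapse = ","),
      n_source_pairs = length(src_pairs),
      uniqueness = if (gene_pairs[[producing]] == 1 &&
                       length(src_pairs) == 1) "unique" else "nonunique",
      producing_transcript = producing,
      directional_subtype = paste0(prod_class, "-", partner_class),
      nat_type = partner_pair$nat_type,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Summarize called NAT-siRNAs
#'
#' @param called data.frame from [call_nat_sirnas()]
#' @return list: `length_histogram` (counts for 18..28 nt),
#'   `subtype_counts` (unique siRNA counts, nat_type x directional
#'   subtype), `tissue_sharing` (counts of tissue-specific vs shared
#'   siRNAs)
#' @export
summarize_sirnas <- function(called) {
  lens <- factor(called$length, levels = 18:28)
  hist <- table(lens)
  uniq <- called[called$uniqueness == "unique", , drop = FALSE]
  subtype <- table(factor(uniq$nat_type, levels = c("cis", "trans")),
                   factor(uniq$directional_subtype,
                          levels = c("PC-PC", "PC-NPC", "NPC-PC", "NPC-NPC")))
  n_tissues <- lengths(strsplit(called$tissues_present, ","))
  sharing <- c(tissue_specific = sum(n_tissues == 1),
               shared = sum(n_tissues > 1))
  list(length_histogram = hist, subtype_counts = subtype,
       tissue_sharing = sharing)
}
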