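#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration for [generate_bundle()].  The defaults
#' describe a small but complete study: a two-chromosome genome carrying
#' planted cis-NAT pairs of every orientation subtype, trans-NAT pairs built
#' by inserting a reverse-complemented segment of one transcript into a
#' transcript on another chromosome, small-RNA data sets with Poisson read
#' placement that is denser inside overlap regions than outside, histone
#' tile calls in which pair genes share their G1/G2 state with a configured
#' concordance, pair-correlated DNA-methylation profiles, and a planted
#' coexpression correlation for a fraction of pairs.
#'
#' @param seed global RNG seed; each layer (geometry, genome, small RNA,
#'   tiles, methylation, expression) uses a stream derived from it by a fixed
#'   offset, so regenerating one layer never perturbs gene placement
#' @param n_chromosomes,chrom_length genome shape (nt)
#' @param n_convergent,n_divergent,n_containing,n_nearby_head,n_nearby_tail
#'   planted cis-NAT pair counts per subtype
#' @param n_trans planted trans-NAT pair count
#' @param trans_region length (nt) of the planted complementary region
#' @param trans_bubble_frac bubble length as a fraction of the planted
#'   region, recycled over trans pairs (0 = perfect complement); the bubble
#'   is a central run of non-complementary substitutions
#' @param n_non_nat_genes genes with no NAT partner (the null pools)
#' @param gene_length,overlap_length,nearby_gap uniform sampling ranges (nt)
#' @param cis_pc_prob,trans_pc_prob probability a pair member is
#'   protein-coding (cis pairs are mostly PC, trans mostly NPC, as observed
#'   in plant NAT surveys)
#' @param biotype_mix named proportions for non-NAT gene biotypes
#' @param sirna_overlap_rate,sirna_background_rate expected distinct
#'   small-RNA loci per nt inside overlap regions and in the remaining gene
#'   body, respectively
#' @param n_smrna_datasets,dataset_presence number of small-RNA data sets
#'   and the probability a planted locus is observed in each
#' @param sirna_length_weights sampling weights for read lengths 18..28
#'   (mass concentrated at 21 and 24 nt by default)
#' @param n_excluded_loci rRNA-like loci (with reads) that the library
#'   filter must remove; one tRNA locus with reads is always added and must
#'   be preserved
#' @param n_multimap_reads reads with two genomic hits (to be removed by the
#'   unique-mapping rule)
#' @param state_probs marginal distribution of gene chromatin states over
#'   G1, G2, G1+G2, NON
#' @param epi_concordance probability the second gene of a pair copies the
#'   first gene's chromatin state (and shares the pair methylation profile)
#' @param tile_width,tile_gap geometry of enriched tiles along marked genes
#' @param meth_beta named list of Beta shape pairs per context (CG, CHG,
#'   CHH) for gene-level mean methylation
#' @param meth_profile_sd,meth_gene_sd across-bin profile noise (shared
#'   within a concordant pair) and per-gene deviation from the shared
#'   profile
#' @param meth_site_spacing,meth_site_coverage cytosine spacing (nt) and
#'   per-site read coverage
#' @param promoter_length promoter extent upstream of the TSS (nt)
#' @param n_expression_samples,expression_rho,coexpr_frac,expr_missing_rate
#'   expression matrix shape, planted pair correlation on the log2 scale,
#'   fraction of NAT pairs planted as coexpressed, and probability a cell is
#'   absent
#' @return a validated list of class `synth_config`
#' @export
synth_config <- function(seed = 1,
                         n_chromosomes = 2, chrom_length = 200000,
                         n_convergent = 5, n_divergent = 5, n_containing = 5,
                         n_nearby_head = 3, n_nearby_tail = 3,
                         n_trans = 4, trans_region = 200, trans_bubble_frac = 0,
                         n_non_nat_genes = 30,
                         gene_length = c(800, 2000),
                         overlap_length = c(100, 300),
                         nearby_gap = c(10, 90),
                         cis_pc_prob = 0.8, trans_pc_prob = 0.35,
                         biotype_mix = c(PC = 0.7, TE = 0.1, lncRNA = 0.1,
                                         other_NPC = 0.1),
                         sirna_overlap_rate = 0.03,
                         sirna_background_rate = 0.005,
                         n_smrna_datasets = 4, dataset_presence = 0.9,
                         sirna_length_weights = c(`18` = 1, `19` = 1, `20` = 2,
                                                  `21` = 10, `22` = 2, `23` = 1,
                                                  `24` = 8, `25` = 1, `26` = 1,
                                                  `27` = 1, `28` = 1),
                         n_excluded_loci = 2, n_multimap_reads = 2,
                         state_probs = c(G1 = 0.45, G2 = 0.3, `G1+G2` = 0.15,
                                         NON = 0.1),
                         epi_concordance = 0.9,
                         tile_width = 100, tile_gap = 50,
                         meth_beta = list(CG = c(7, 3), CHG = c(3, 7),
                                          CHH = c(2, 18)),
                         meth_profile_sd = 0.15, meth_gene_sd = 0.03,
                         meth_site_spacing = 30, meth_site_coverage = 20,
                         promoter_length = 1000,
                         n_expression_samples = 15, expression_rho = 0.95,
                         coexpr_frac = 0.6, expr_missing_rate = 0.1) {
  cfg <- as.list(environment())
  counts <- c(n_chromosomes, chrom_length, n_convergent, n_divergent,
              n_containing, n_nearby_head, n_nearby_tail, n_trans,
              n_non_nat_genes)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sirna_overlap_rate < 0 || sirna_background_rate < 0) {
    stop("siRNA rates must be >= 0")
  }
  probs <- c(cis_pc_prob, trans_pc_prob, dataset_presence, epi_concordance,
             coexpr_frac, expr_missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(expression_rho) > 1) stop("expression_rho must lie in [-1, 1]")
  if (abs(sum(state_probs) - 1) > 1e-8) stop("state_probs must sum to 1")
  class(cfg) <- "synth_config"
  cfg
}

.layer_seed <- function(cfg, layer) {
  offsets <- c(geometry = 0L, genome = 101L, smrna = 202L, tiles = 303L,
               methylation = 404L, expression = 505L, candidates = 606L)
  cfg$seed + offsets[[layer]]
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- geometry --------------------------------------------------------------

.synth_geometry <- function(cfg) {
  set.seed(.layer_seed(cfg, "geometry"))
  slot_size <- max(2 * cfg$gene_length[2] + 2 * cfg$promoter_length + 400, 6000)
  margin <- cfg$promoter_length + 100
  per_chrom <- floor((cfg$chrom_length - margin) / slot_size)
  n_cis <- cfg$n_convergent + cfg$n_divergent + cfg$n_containing +
    cfg$n_nearby_head + cfg$n_nearby_tail
  n_units <- n_cis + 2 * cfg$n_trans + cfg$n_non_nat_genes
  if (n_units > per_chrom * cfg$n_chromosomes) {
    stop("planted geometry impossible on chromosome length: need ", n_units,
         " gene slots, have ", per_chrom * cfg$n_chromosomes)
  }
  all_slots <- expand.grid(chrom_i = seq_len(cfg$n_chromosomes),
                           slot = seq_len(per_chrom))
  slots <- all_slots[sample.int(nrow(all_slots), n_units), ]
  slots$chrom <- paste0("chr", slots$chrom_i)
  slots$origin <- margin + (slots$slot - 1) * slot_size

  tx <- list(); truth <- list(); gi <- 0L; pi_ <- 0L
  new_gene <- function(chrom, start, end, strand, biotype) {
    gi <<- gi + 1L
    id <- sprintf("G%04d", gi)
    cds_start <- cds_end <- NA_real_
    if (biotype == "PC") {
      len <- end - start
      cds_start <- start + round(0.2 * len)
      cds_end <- end - round(0.2 * len)
    }
    data.frame(transcript_id = paste0(id, ".1"), gene_id = id, chrom = chrom,
               start = start, end = end, strand = strand, biotype = biotype,
               coding_class = if (biotype == "PC") "PC" else "NPC",
               cds_start = cds_start, cds_end = cds_end,
               stringsAsFactors = FALSE)
  }
  npc_types <- c("lncRNA", "TE", "other_NPC")
  draw_biotype <- function(pc_prob) {
    if (stats::runif(1) < pc_prob) "PC"
    else sample(npc_types, 1, prob = c(0.5, 0.3, 0.2))
  }

  si <- 0L
  next_slot <- function() {
    si <<- si + 1L
    slots[si, ]
  }
  add_cis <- function(subtype) {
    s <- next_slot()
    la <- runif_int(1, cfg$gene_length)
    lb <- runif_int(1, cfg$gene_length)
    if (subtype == "containing") la <- max(la, lb + 200)
    a_start <- s$origin
    if (subtype == "convergent") {
      ov <- min(runif_int(1, cfg$overlap_length), la - 50, lb - 50)
      a <- new_gene(s$chrom, a_start, a_start + la, "+", draw_biotype(cfg$cis_pc_prob))
      b <- new_gene(s$chrom, a_start + la - ov, a_start + la - ov + lb, "-",
                    draw_biotype(cfg$cis_pc_prob))
      o <- c(a_start + la - ov, a_start + la); gap <- NA
    } else if (subtype == "divergent") {
      ov <- min(runif_int(1, cfg$overlap_length), la - 50, lb - 50)
      b <- new_gene(s$chrom, a_start, a_start + lb, "-", draw_biotype(cfg$cis_pc_prob))
      a <- new_gene(s$chrom, a_start + lb - ov, a_start + lb - ov + la, "+",
                    draw_biotype(cfg$cis_pc_prob))
      o <- c(a_start + lb - ov, a_start + lb); gap <- NA
    } else if (subtype == "containing") {
      inset <- runif_int(1, c(50, 150))
      a <- new_gene(s$chrom, a_start, a_start + la, "+", draw_biotype(cfg$cis_pc_prob))
      b <- new_gene(s$chrom, a_start + inset, a_start + inset + lb, "-",
                    draw_biotype(cfg$cis_pc_prob))
      o <- c(a_start + inset, a_start + inset + lb); gap <- NA
    } else if (subtype == "nearby_tail_to_tail") {
      gap <- runif_int(1, cfg$nearby_gap)
      a <- new_gene(s$chrom, a_start, a_start + la, "+", draw_biotype(cfg$cis_pc_prob))
      b <- new_gene(s$chrom, a_start + la + gap, a_start + la + gap + lb, "-",
                    draw_biotype(cfg$cis_pc_prob))
      o <- c(NA, NA)
    } else { # nearby_head_to_head
      gap <- runif_int(1, cfg$nearby_gap)
      b <- new_gene(s$chrom, a_start, a_start + lb, "-", draw_biotype(cfg$cis_pc_prob))
      a <- new_gene(s$chrom, a_start + lb + gap, a_start + lb + gap + la, "+",
                    draw_biotype(cfg$cis_pc_prob))
      o <- c(NA, NA)
    }
    tx[[length(tx) + 1L]] <<- a; tx[[length(tx) + 1L]] <<- b
    pi_ <<- pi_ + 1L
    truth[[length(truth) + 1L]] <<- data.frame(
      pair_id = sprintf("P%04d", pi_), nat_type = "cis", subtype = subtype,
      transcript_a = a$transcript_id, transcript_b = b$transcript_id,
      chrom_a = s$chrom, chrom_b = s$chrom,
      overlap_start = o[1], overlap_end = o[2], gap = gap,
      region_a_start = NA, region_a_end = NA,
      region_b_start = NA, region_b_end = NA,
      bubble_frac = NA, stringsAsFactors = FALSE)
  }
  for (st in c("convergent", "divergent", "containing", "nearby_head_to_head",
               "nearby_tail_to_tail")) {
    n <- switch(st, convergent = cfg$n_convergent, divergent = cfg$n_divergent,
                containing = cfg$n_containing,
                nearby_head_to_head = cfg$n_nearby_head,
                nearby_tail_to_tail = cfg$n_nearby_tail)
    for (i in seq_len(n)) add_cis(st)
  }

  bubble <- rep_len(cfg$trans_bubble_frac, cfg$n_trans)
  for (i in seq_len(cfg$n_trans)) {
    sa <- next_slot(); sb <- next_slot()
    la <- max(runif_int(1, cfg$gene_length), cfg$trans_region + 200)
    lb <- max(runif_int(1, cfg$gene_length), cfg$trans_region + 200)
    a <- new_gene(sa$chrom, sa$origin, sa$origin + la, "+",
                  draw_biotype(cfg$trans_pc_prob))
    b <- new_gene(sb$chrom, sb$origin, sb$origin + lb, "+",
                  draw_biotype(cfg$trans_pc_prob))
    a_off <- floor((la - cfg$trans_region) / 2)
    b_off <- floor((lb - cfg$trans_region) / 2)
    tx[[length(tx) + 1L]] <- a; tx[[length(tx) + 1L]] <- b
    pi_ <- pi_ + 1L
    truth[[length(truth) + 1L]] <- data.frame(
      pair_id = sprintf("P%04d", pi_), nat_type = "trans", subtype = "trans",
      transcript_a = a$transcript_id, transcript_b = b$transcript_id,
      chrom_a = a$chrom, chrom_b = b$chrom,
      overlap_start = NA, overlap_end = NA, gap = NA,
      region_a_start = a$start + a_off, region_a_end = a$start + a_off + cfg$trans_region,
      region_b_start = b$start + b_off, region_b_end = b$start + b_off + cfg$trans_region,
      bubble_frac = bubble[i], stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n_non_nat_genes)) {
    s <- next_slot()
    len <- runif_int(1, cfg$gene_length)
    bt <- sample(names(cfg$biotype_mix), 1, prob = cfg$biotype_mix)
    tx[[length(tx) + 1L]] <- new_gene(s$chrom, s$origin, s$origin + len,
                                      sample(c("+", "-"), 1), bt)
  }

  transcripts <- do.call(rbind, tx)
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  exons <- data.frame(transcript_id = transcripts$transcript_id,
                      chrom = transcripts$chrom, start = transcripts$start,
                      end = transcripts$end, strand = transcripts$strand,
                      stringsAsFactors = FALSE)
  list(transcripts = transcripts, exons = exons, truth = truth)
}

# ---- genome & trans-NAT sequence planting ---------------------------------

.synth_genome <- function(cfg, geom) {
  set.seed(.layer_seed(cfg, "genome"))
  genome <- stats::setNames(
    vapply(seq_len(cfg$n_chromosomes), function(i) {
      intToUtf8(sample(utf8ToInt("ACGT"), cfg$chrom_length, replace = TRUE))
    }, character(1)),
    paste0("chr", seq_len(cfg$n_chromosomes)))

  tr <- geom$truth[geom$truth$nat_type == "trans", , drop = FALSE]
  for (i in seq_len(NROW(tr))) {
    seg <- substr(genome[[tr$chrom_a[i]]], tr$region_a_start[i] + 1,
                  tr$region_a_end[i])
    bl <- round(tr$bubble_frac[i] * nchar(seg))
    if (!is.na(bl) && bl > 0) {
      # delete a central run from the copied segment: those bases of the
      # first transcript have no partner, forming one unpaired bubble
      from <- floor((nchar(seg) - bl) / 2) + 1
      seg <- paste0(substr(seg, 1, from - 1),
                    substr(seg, from + bl, nchar(seg)))
    }
    ins <- revcomp(seg)
    g <- genome[[tr$chrom_b[i]]]
    substr(g, tr$region_b_start[i] + 1,
           tr$region_b_start[i] + nchar(ins)) <- ins
    genome[[tr$chrom_b[i]]] <- g
  }
  genome
}

transcript_sequences <- function(transcripts, genome) {
  seqs <- vapply(seq_len(nrow(transcripts)), function(i) {
    s <- substr(genome[[transcripts$chrom[i]]], transcripts$start[i] + 1,
                transcripts$end[i])
    if (transcripts$strand[i] == "-") revcomp(s) else s
  }, character(1))
  stats::setNames(seqs, transcripts$transcript_id)
}

# ---- small RNA layer -------------------------------------------------------

# overlap (dsRNA-forming) regions per planted pair, one row per region
.truth_overlap_regions <- function(truth) {
  if (is.null(truth)) return(NULL)
  cis <- truth[truth$nat_type == "cis" & !is.na(truth$overlap_start), ]
  tr <- truth[truth$nat_type == "trans", ]
  rbind(
    if (nrow(cis)) data.frame(pair_id = cis$pair_id, chrom = cis$chrom_a,
                              start = cis$overlap_start, end = cis$overlap_end,
                              stringsAsFactors = FALSE),
    if (nrow(tr)) data.frame(pair_id = rep(tr$pair_id, 2),
                             chrom = c(tr$chrom_a, tr$chrom_b),
                             start = c(tr$region_a_start, tr$region_b_start),
                             end = c(tr$region_a_end, tr$region_b_end),
                             stringsAsFactors = FALSE))
}

.synth_smrna <- function(cfg, geom, genome) {
  set.seed(.layer_seed(cfg, "smrna"))
  tx <- geom$transcripts
  regions <- .truth_overlap_regions(geom$truth)
  lens <- as.integer(names(cfg$sirna_length_weights))

  # background support: gene spans minus overlap regions
  bg <- lapply(seq_len(nrow(tx)), function(i) {
    span <- IRanges::IRanges(tx$start[i] + 1, tx$end[i])
    if (!is.null(regions)) {
      ov <- regions[regions$chrom == tx$chrom[i], , drop = FALSE]
      if (nrow(ov)) {
        span <- IRanges::setdiff(span, IRanges::IRanges(ov$start + 1, ov$end))
      }
    }
    if (length(span) == 0) return(NULL)
    data.frame(chrom = tx$chrom[i], start = IRanges::start(span) - 1,
               end = IRanges::end(span), stringsAsFactors = FALSE)
  })
  bg <- do.call(rbind, bg[!vapply(bg, is.null, logical(1))])

  draw_loci <- function(reg, rate) {
    out <- list()
    for (i in seq_len(NROW(reg))) {
      L <- reg$end[i] - reg$start[i]
      n <- stats::rpois(1, rate * L)
      if (n == 0) next
      rl <- sample(lens, n, replace = TRUE, prob = cfg$sirna_length_weights)
      rl <- pmin(rl, L)
      st <- reg$start[i] + vapply(L - rl, function(m) sample.int(m + 1, 1) - 1L,
                                  integer(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = reg$chrom[i], start = st, end = st + rl,
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  loci <- rbind(
    if (!is.null(regions)) draw_loci(regions, cfg$sirna_overlap_rate),
    if (!is.null(bg)) draw_loci(bg, cfg$sirna_background_rate))
  if (!is.null(loci)) {
    loci <- unique(loci)
    loci$sequence <- vapply(seq_len(nrow(loci)), function(i) {
      s <- substr(genome[[loci$chrom[i]]], loci$start[i] + 1, loci$end[i])
      if (loci$strand[i] == "-") revcomp(s) else s
    }, character(1))
    loci <- loci[!duplicated(loci$sequence), , drop = FALSE]
  }

  datasets <- data.frame(
    dataset_id = paste0("D", seq_len(cfg$n_smrna_datasets)),
    tissue = rep_len(c("seedling", "leaf", "flower", "root"),
                     cfg$n_smrna_datasets),
    stringsAsFactors = FALSE)

  hits <- list()
  if (NROW(loci)) {
    present <- matrix(stats::runif(NROW(loci) * cfg$n_smrna_datasets) <
                        cfg$dataset_presence, nrow = NROW(loci))
    idx <- which(present, arr.ind = TRUE)
    if (nrow(idx)) {
      i <- idx[, 1]; d <- idx[, 2]
      hits[[1]] <- data.frame(
        read_id = sprintf("r%05d_%s", i, datasets$dataset_id[d]),
        sequence = loci$sequence[i], chrom = loci$chrom[i],
        start = loci$start[i], end = loci$end[i], strand = loci$strand[i],
        dataset_id = datasets$dataset_id[d],
        count = 1L + stats::rpois(nrow(idx), 2), stringsAsFactors = FALSE)
    }
  }

  # excluded-class loci (rRNA) plus one preserved tRNA locus, in intergenic
  # space near the chromosome start
  exclusion <- NULL
  cls <- c(rep("rRNA", cfg$n_excluded_loci), "tRNA")
  for (j in seq_along(cls)) {
    st <- 100 + (j - 1) * 300
    exclusion <- rbind(exclusion, data.frame(
      chrom = "chr1", start = st, end = st + 120, mark = cls[j],
      stringsAsFactors = FALSE))
    seq_ <- substr(genome[["chr1"]], st + 11, st + 31)
    hits[[length(hits) + 1L]] <- data.frame(
      read_id = sprintf("x%02d_D1", j), sequence = seq_, chrom = "chr1",
      start = st + 10, end = st + 31, strand = "+", dataset_id = "D1",
      count = 1L, stringsAsFactors = FALSE)
  }
  # multi-mappers: one read id with two hit rows
  for (j in seq_len(cfg$n_multimap_reads)) {
    seq_ <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
    for (pos in c(5000 + j * 50, 9000 + j * 50)) {
      hits[[length(hits) + 1L]] <- data.frame(
        read_id = sprintf("mm%02d_D1", j), sequence = seq_, chrom = "chr1",
        start = pos, end = pos + 21, strand = "+", dataset_id = "D1",
        count = 1L, stringsAsFactors = FALSE)
    }
  }
  smrna <- do.call(rbind, hits)
  smrna$length <- nchar(smrna$sequence)
  smrna <- smrna[c("read_id", "sequence", "length", "chrom", "start", "end",
                   "strand", "dataset_id", "count")]
  list(smrna = smrna, datasets = datasets, exclusion = exclusion, loci = loci)
}

# ---- chromatin tiles -------------------------------------------------------

G1_MARKS <- c("H3K4me2", "H3K4me3", "H3K36me3", "H2Bub")
G2_MARKS <- c("H3K27me1", "H3K27me3")

.synth_states <- function(cfg, geom) {
  tx <- geom$transcripts
  states <- stats::setNames(rep(NA_character_, nrow(tx)), tx$transcript_id)
  draw <- function(n) sample(names(cfg$state_probs), n, replace = TRUE,
                             prob = cfg$state_probs)
  tr <- geom$truth
  for (i in seq_len(NROW(tr))) {
    a <- tr$transcript_a[i]; b <- tr$transcript_b[i]
    states[a] <- draw(1)
    states[b] <- if (stats::runif(1) < cfg$epi_concordance) states[a] else draw(1)
  }
  rest <- is.na(states)
  states[rest] <- draw(sum(rest))
  states
}

.synth_tiles <- function(cfg, geom, states) {
  tx <- geom$transcripts
  tiles <- list()
  for (i in seq_len(nrow(tx))) {
    st <- states[tx$transcript_id[i]]
    marks <- switch(st,
      G1 = sample(G1_MARKS, 2),
      G2 = G2_MARKS,
      `G1+G2` = c(sample(G1_MARKS, 1), sample(G2_MARKS, 1)),
      NON = character())
    for (m in marks) {
      pos <- seq(tx$start[i], tx$end[i] - cfg$tile_width,
                 by = cfg$tile_width + cfg$tile_gap)
      tiles[[length(tiles) + 1L]] <- data.frame(
        chrom = tx$chrom[i], start = pos, end = pos + cfg$tile_width,
        mark = m, stringsAsFactors = FALSE)
    }
  }
  if (length(tiles)) do.call(rbind, tiles) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mark = character(), stringsAsFactors = FALSE)
}

# ---- methylation -----------------------------------------------------------

.synth_methylation <- function(cfg, geom) {
  tx <- geom$transcripts
  truth <- geom$truth
  n_bins <- 20L
  contexts <- c("CG", "CHG", "CHH")
  regions <- c("promoter", "body")

  # shared pair profiles: pair members deviate little from a common
  # per-bin profile; unpaired genes draw independent profiles
  partner <- stats::setNames(rep(NA_character_, nrow(tx)), tx$transcript_id)
  concordant <- stats::setNames(rep(FALSE, nrow(tx)), tx$transcript_id)
  for (i in seq_len(NROW(truth))) {
    a <- truth$transcript_a[i]; b <- truth$transcript_b[i]
    if (stats::runif(1) < cfg$epi_concordance) {
      partner[b] <- a
      concordant[c(a, b)] <- TRUE
    }
  }
  profile <- list()
  gene_profile <- function(id, region, ctx) {
    key <- paste(id, region, ctx)
    if (!is.null(profile[[key]])) return(profile[[key]])
    src <- partner[id]
    if (!is.na(src)) {
      base <- gene_profile(src, region, ctx)
      p <- clamp01(base + stats::rnorm(n_bins, 0, cfg$meth_gene_sd))
    } else {
      shp <- cfg$meth_beta[[ctx]]
      m <- stats::rbeta(1, shp[1], shp[2])
      p <- clamp01(m + stats::rnorm(n_bins, 0, cfg$meth_profile_sd))
    }
    profile[[key]] <<- p
    p
  }

  rows <- vector("list", nrow(tx) * length(regions) * length(contexts))
  ri <- 0L
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    for (region in regions) {
      if (region == "body") {
        rs <- tx$start[i]; re <- tx$end[i]
      } else if (tx$strand[i] == "+") {
        rs <- max(0, tx$start[i] - cfg$promoter_length); re <- tx$start[i]
      } else {
        rs <- tx$end[i]; re <- tx$end[i] + cfg$promoter_length
      }
      if (re - rs < n_bins) next
      for (ctx in contexts) {
        p <- gene_profile(id, region, ctx)
        off <- match(ctx, contexts) * 7  # stagger contexts
        pos <- seq(rs + off, re - 1, by = cfg$meth_site_spacing)
        if (!length(pos)) next
        bin <- pmin(floor((pos - rs) / ((re - rs) / n_bins)) + 1, n_bins)
        if (tx$strand[i] == "-") bin <- n_bins + 1L - bin
        lev <- p[bin]
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          chrom = tx$chrom[i], pos = pos,
          strand = sample(c("+", "-"), length(pos), replace = TRUE),
          context = ctx,
          methylated = stats::rbinom(length(pos), cfg$meth_site_coverage, lev),
          total = cfg$meth_site_coverage, stringsAsFactors = FALSE)
      }
    }
  }
  sites <- do.call(rbind, rows[seq_len(ri)])
  sites[order(sites$chrom, sites$pos), ]
}

# ---- expression ------------------------------------------------------------

.synth_expression <- function(cfg, geom) {
  tx <- geom$transcripts
  n_s <- cfg$n_expression_samples
  z <- matrix(stats::rnorm(nrow(tx) * n_s, mean = 3, sd = 1), nrow = nrow(tx),
              dimnames = list(tx$transcript_id,
                              paste0("S", seq_len(n_s))))
  truth <- geom$truth
  coexpr <- stats::setNames(rep(NA_real_, NROW(truth)),
                            if (NROW(truth)) truth$pair_id else NULL)
  for (i in seq_len(NROW(truth))) {
    if (stats::runif(1) < cfg$coexpr_frac) {
      rho <- cfg$expression_rho
      a <- truth$transcript_a[i]; b <- truth$transcript_b[i]
      za <- z[a, ]
      z[b, ] <- 3 + rho * (za - 3) + sqrt(1 - rho^2) * stats::rnorm(n_s)
      coexpr[i] <- rho
    }
  }
  fpkm <- round(2^z, 3)
  miss <- matrix(stats::runif(length(fpkm)) < cfg$expr_missing_rate,
                 nrow = nrow(fpkm))
  fpkm[miss] <- NA
  list(expression = fpkm, planted_rho = coexpr)
}

# ---- bundle ----------------------------------------------------------------

#' Generate a complete synthetic input bundle
#'
#' Produces every input the pipeline reads (annotation, genome and
#' transcript sequences, small-RNA hit table with data-set metadata and an
#' exclusion annotation, chromatin tiles, per-cytosine methylation calls,
#' expression matrix) with planted structure recorded in a truth table.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [synth_config()]
#' @param dir optional output directory; when given, all fixtures are
#'   written in the exact formats the `read_*` functions consume
#' @return a list with elements `catalog` (transcripts + exons), `genome`,
#'   `tx_seqs`, `smrna`, `datasets`, `exclusion`, `tiles`, `states` (planted
#'   chromatin states), `methylation`, `expression`, `truth`, `config`
#' @export
generate_bundle <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  geom <- .synth_geometry(config)
  genome <- .synth_genome(config, geom)
  tx_seqs <- transcript_sequences(geom$transcripts, genome)
  sm <- .synth_smrna(config, geom, genome)
  set.seed(.layer_seed(config, "tiles"))
  states <- .synth_states(config, geom)
  tiles <- .synth_tiles(config, geom, states)
  set.seed(.layer_seed(config, "methylation"))
  meth <- .synth_methylation(config, geom)
  set.seed(.layer_seed(config, "expression"))
  expr <- .synth_expression(config, geom)

  truth <- geom$truth
  if (!is.null(truth)) {
    truth$state_a <- unname(states[truth$transcript_a])
    truth$state_b <- unname(states[truth$transcript_b])
    truth$planted_rho <- unname(expr$planted_rho)
  }

  bundle <- list(
    catalog = list(transcripts = geom$transcripts, exons = geom$exons),
    genome = genome, tx_seqs = tx_seqs,
    smrna = sm$smrna, datasets = sm$datasets, exclusion = sm$exclusion,
    tiles = tiles, states = states, methylation = meth,
    expression = expr$expression, truth = truth, config = config)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gff3(bundle$catalog, file.path(dir, "annotation.gff3"))
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_fasta(tx_seqs, file.path(dir, "transcripts.fa"))
    write_tsv(sm$smrna[, setdiff(names(sm$smrna), "length")],
              file.path(dir, "smrna.tsv"), params = list(seed = config$seed))
    write_tsv(sm$datasets, file.path(dir, "datasets.tsv"))
    write_tiles(sm$exclusion, file.path(dir, "exclusion.bed"))
    write_tiles(tiles, file.path(dir, "tiles.bed"))
    write_tsv(meth, file.path(dir, "methylation.tsv"))
    write_expression_matrix(bundle$expression, file.path(dir, "expression.tsv"))
    if (!is.null(truth)) write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  invisible(bundle)
}

#' Planted-truth table for a configuration
#'
#' Regenerates the deterministic truth table (planted pairs, subtypes,
#' overlap coordinates, chromatin states, planted expression correlation)
#' for the same configuration and seed used by [generate_bundle()].
#'
#' @param config a [synth_config()]
#' @return the truth data.frame
#' @export
truth_table <- function(config) {
  generate_bundle(config)$truth
}
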