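#' @importFrom utils read.delim write.table head tail
NULL

BIOTYPES <- c("PC", "lncRNA", "TE", "pseudogene", "tRNA", "other_NPC")

# fallback GFF3 feature-type -> biotype mapping, used when the transcript
# carries no biotype attribute
.TYPE_BIOTYPE <- c(
  mRNA = "PC",
  transcript = "other_NPC",
  lnc_RNA = "lncRNA",
  lincRNA = "lncRNA",
  antisense_lncRNA = "lncRNA",
  tRNA = "tRNA",
  pseudogenic_transcript = "pseudogene",
  transposable_element = "TE",
  ncRNA = "other_NPC")

.TRANSCRIPT_TYPES <- names(.TYPE_BIOTYPE)

normalize_biotype <- function(x) {
  x <- as.character(x)
  unknown <- !is.na(x) & !x %in% BIOTYPES
  if (any(unknown)) {
    warning("unknown biotype(s) mapped to other_NPC: ",
            paste(unique(x[unknown]), collapse = ", "))
    x[unknown] <- "other_NPC"
  }
  x
}

#' Read a GFF3 annotation into a transcript catalog
#'
#' Parses a gene/transcript/exon (and optional CDS) hierarchy and converts
#' GFF3 1-based inclusive coordinates to the internal 0-based half-open
#' convention.  Transcripts without exon children get a single exon
#' synthesized from the transcript span.
#'
#' @param path GFF3 file
#' @param biotype_attr attribute key holding the biotype; when absent the
#'   feature type is mapped through a fixed fallback table (mRNA is
#'   protein-coding, lnc_RNA and friends are lncRNA, ...). Biotypes outside
#'   the six-class vocabulary (PC, lncRNA, TE, pseudogene, tRNA, other_NPC)
#'   collapse to `other_NPC` with a warning.
#' @return a list with elements `transcripts` (data.frame: transcript_id,
#'   gene_id, chrom, start, end, strand, biotype, coding_class, cds_start,
#'   cds_end) and `exons` (data.frame: transcript_id, chrom, start, end,
#'   strand).  `coding_class` is `"PC"` iff biotype is PC, else `"NPC"`.
#' @export
read_gff3 <- function(path, biotype_attr = "biotype") {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stop("malformed GFF3 line ", body[which(nfield != 9L)[1]],
         " in ", path, " (expected 9 tab-separated fields)")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand for feature(s): ",
         paste(utils::head(gr$ID[!strand %in% c("+", "-")], 3), collapse = ", "))
  }
  type <- as.character(gr$type)
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))

  is_tx <- type %in% .TRANSCRIPT_TYPES
  tx_ids <- gr$ID[is_tx]
  biotype <- if (biotype_attr %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)[[biotype_attr]][is_tx]
  } else {
    rep(NA_character_, sum(is_tx))
  }
  fallback <- is.na(biotype)
  biotype[fallback] <- unname(.TYPE_BIOTYPE[type[is_tx][fallback]])
  biotype <- normalize_biotype(biotype)

  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = ifelse(is.na(parent[is_tx]), tx_ids, parent[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_tx],
    start = GenomicRanges::start(gr)[is_tx] - 1,
    end = as.numeric(GenomicRanges::end(gr))[is_tx],
    strand = strand[is_tx],
    biotype = biotype,
    stringsAsFactors = FALSE)
  transcripts$coding_class <- ifelse(transcripts$biotype == "PC", "PC", "NPC")
  transcripts$cds_start <- NA_real_
  transcripts$cds_end <- NA_real_

  is_exon <- type == "exon"
  if (any(is_exon)) {
    ep <- parent[is_exon]
    orphan <- !ep %in% tx_ids
    if (any(orphan)) {
      stop("exon with unresolvable parent id: ", unique(ep[orphan])[1])
    }
    exons <- data.frame(
      transcript_id = ep,
      chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
      start = GenomicRanges::start(gr)[is_exon] - 1,
      end = as.numeric(GenomicRanges::end(gr))[is_exon],
      strand = strand[is_exon],
      stringsAsFactors = FALSE)
  } else {
    exons <- data.frame(transcript_id = character(), chrom = character(),
                        start = numeric(), end = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  # synthesize single exons for exon-less transcripts
  missing_tx <- setdiff(tx_ids, exons$transcript_id)
  if (length(missing_tx)) {
    m <- transcripts[match(missing_tx, transcripts$transcript_id), ]
    exons <- rbind(exons, data.frame(
      transcript_id = m$transcript_id, chrom = m$chrom, start = m$start,
      end = m$end, strand = m$strand, stringsAsFactors = FALSE))
  }
  exons <- exons[order(exons$transcript_id, exons$start), ]
  rownames(exons) <- NULL

  is_cds <- type == "CDS"
  if (any(is_cds)) {
    cp <- parent[is_cds]
    cs <- GenomicRanges::start(gr)[is_cds] - 1
    ce <- as.numeric(GenomicRanges::end(gr))[is_cds]
    for (id in unique(cp)) {
      i <- match(id, transcripts$transcript_id)
      if (is.na(i)) stop("CDS with unresolvable parent id: ", id)
      transcripts$cds_start[i] <- min(cs[cp == id])
      transcripts$cds_end[i] <- max(ce[cp == id])
    }
  }
  rownames(transcripts) <- NULL
  list(transcripts = transcripts, exons = exons)
}

#' Write a transcript catalog as GFF3
#'
#' Inverse of [read_gff3()] on catalogs produced by this package: internal
#' 0-based half-open coordinates become 1-based inclusive.
#'
#' @param catalog list with `transcripts` and `exons` as from [read_gff3()]
#' @param path output file
#' @export
write_gff3 <- function(catalog, path) {
  tx <- catalog$transcripts
  ex <- catalog$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- unique(tx[, c("gene_id", "chrom", "strand")])
  for (g in seq_len(nrow(genes))) {
    gt <- tx[tx$gene_id == genes$gene_id[g], ]
    writeLines(sprintf("%s\tnatscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom[g], min(gt$start) + 1, max(gt$end),
                       genes$strand[g], genes$gene_id[g]), con)
    for (i in seq_len(nrow(gt))) {
      ftype <- if (gt$biotype[i] == "PC") "mRNA" else "transcript"
      writeLines(sprintf("%s\tnatscape\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
                         gt$chrom[i], ftype, gt$start[i] + 1, gt$end[i],
                         gt$strand[i], gt$transcript_id[i], gt$gene_id[i],
                         gt$biotype[i]), con)
      ei <- ex[ex$transcript_id == gt$transcript_id[i], ]
      if (nrow(ei)) {
        writeLines(sprintf("%s\tnatscape\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                           ei$chrom, ei$start + 1, ei$end, ei$strand,
                           ei$transcript_id), con)
      }
      if (!is.na(gt$cds_start[i])) {
        writeLines(sprintf("%s\tnatscape\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                           gt$chrom[i], gt$cds_start[i] + 1, gt$cds_end[i],
                           gt$strand[i], gt$transcript_id[i]), con)
      }
    }
  }
  invisible(path)
}

# ---- generic TSV helpers ---------------------------------------------------

#' Write a TSV with a `#` comment block recording parameters
#'
#' @param df data.frame
#' @param path output path
#' @param params named list recorded as `# key: value` comment lines
#' @export
write_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params)) {
    writeLines(sprintf("# %s: %s", k, paste(params[[k]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read a small-RNA hit table
#'
#' One row per genomic hit; multiple rows per read id are multi-mappers
#' (removed later by [build_library()]).  Columns: read_id, sequence, chrom,
#' start, end, strand, dataset_id, count.
#'
#' @param path TSV file
#' @return data.frame of hits with a derived `length` column; the span of
#'   every hit must equal the sequence length
#' @export
read_smrna_table <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      length = integer(), chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      dataset_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  need <- c("read_id", "sequence", "chrom", "start", "end", "strand",
            "dataset_id", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("smRNA table missing column(s): ", paste(miss, collapse = ", "))
  df$length <- nchar(df$sequence)
  bad <- df$end - df$start != df$length
  if (any(bad)) {
    stop("hit span does not match sequence length for read ",
         df$read_id[which(bad)[1]])
  }
  df[c("read_id", "sequence", "length", "chrom", "start", "end", "strand",
       "dataset_id", "count")]
}

#' Read per-cytosine methylation calls
#'
#' Columns: chrom, pos (0-based), strand, context (CG/CHG/CHH), methylated,
#' total.
#'
#' @param path TSV file
#' @return data.frame of methylation sites
#' @export
read_methylation_table <- function(path) {
  df <- read_tsv(path)
  bad_ctx <- !df$context %in% c("CG", "CHG", "CHH")
  if (any(bad_ctx)) {
    stop("unknown methylation context: ", unique(df$context[bad_ctx])[1])
  }
  if (any(df$methylated < 0) || any(df$total < 0)) {
    stop("negative methylation counts")
  }
  if (any(df$methylated > df$total)) {
    stop("methylated count exceeds total coverage")
  }
  df
}

#' Read chromatin tiles or domains from BED4
#'
#' BED name column = mark name; coordinates are BED-native 0-based half-open
#' and are kept as-is.
#'
#' @param path BED4 file
#' @return data.frame with chrom, start, end, mark
#' @export
read_tiles <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             mark = gr$name, stringsAsFactors = FALSE)
}

#' @rdname read_tiles
#' @param tiles data.frame with chrom, start, end, mark
#' @export
write_tiles <- function(tiles, path) {
  df <- data.frame(tiles$chrom, format(tiles$start, scientific = FALSE, trim = TRUE),
                   format(tiles$end, scientific = FALSE, trim = TRUE), tiles$mark)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (transcripts x samples)
#'
#' Blank cells are *absent* observations (NA), not zeros: downstream
#' data-set-presence rules count non-missing cells only.
#'
#' @param path TSV with a `transcript_id` first column
#' @return numeric matrix with transcript ids as rownames, NA = absent
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression_matrix
#' @param mat numeric matrix, rownames = transcript ids
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}
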