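#' Expression correlation of a NAT pair
#'
#' Genes present (non-missing) in fewer than `min_datasets` samples are
#' excluded; the Pearson correlation is computed over samples where both
#' genes are present, and is undefined when fewer than `min_datasets`
#' samples are shared or either vector has zero variance.
#'
#' @param expr expression matrix (transcripts x samples, NA = absent)
#' @param a,b transcript ids
#' @param min_datasets presence threshold
#' @return list: pcc (NA if undefined), n_shared, reason
#' @export
expression_pcc <- function(expr, a, b, min_datasets = 3) {
  if (!a %in% rownames(expr) || !b %in% rownames(expr)) {
    return(list(pcc = NA_real_, n_shared = 0L, reason = "not in matrix"))
  }
  va <- expr[a, ]; vb <- expr[b, ]
  if (sum(!is.na(va)) < min_datasets || sum(!is.na(vb)) < min_datasets) {
    return(list(pcc = NA_real_, n_shared = 0L,
                reason = "present in fewer than min_datasets samples"))
  }
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < min_datasets) {
    return(list(pcc = NA_real_, n_shared = sum(ok),
                reason = "fewer than min_datasets shared samples"))
  }
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    return(list(pcc = NA_real_, n_shared = sum(ok), reason = "zero variance"))
  }
  list(pcc = stats::cor(va[ok], vb[ok]), n_shared = sum(ok),
       reason = NA_character_)
}

#' Build the NAT coexpression network
#'
#' One candidate edge per NAT pair; an edge is kept iff the expression
#' correlation is defined and `|PCC|` reaches the threshold (inclusive by
#' default; `strict_gt = TRUE` requires a strict inequality).
#'
#' @param pairs combined NAT pair table (needs pair_id, transcript_a/b,
#'   nat_type)
#' @param expr expression matrix
#' @param threshold absolute correlation threshold
#' @param strict_gt require `|PCC| > threshold` instead of `>=`
#' @param min_datasets presence threshold passed to [expression_pcc()]
#' @return data.frame of all pairs with pcc, n_shared, undefined_reason and
#'   logical `edge`
#' @export
build_network <- function(pairs, expr, threshold = 0.8, strict_gt = FALSE,
                          min_datasets = 3) {
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    expression_pcc(expr, pairs$transcript_a[k], pairs$transcript_b[k],
                   min_datasets)
  })
  pcc <- vapply(res, `[[`, numeric(1), "pcc")
  edges <- data.frame(
    pair_id = pairs$pair_id, transcript_a = pairs$transcript_a,
    transcript_b = pairs$transcript_b, nat_type = pairs$nat_type,
    pcc = pcc,
    n_shared = vapply(res, `[[`, integer(1), "n_shared"),
    undefined_reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  edges$edge <- !is.na(pcc) &
    (if (strict_gt) abs(pcc) > threshold else abs(pcc) >= threshold)
  edges
}

#' Annotate network edges with NAT-siRNA and epigenetic features
#'
#' `produces_nat_sirna` is TRUE iff a called NAT-siRNA lists the pair among
#' its source pairs.  `modification_similarity` is the Pearson correlation
#' of the two genes' concatenated per-mark binary domain-overlap profiles
#' over body bins.  The feature label is `both` / `siRNA` / `epigenetic` /
#' `none`; a pair with an undefined similarity falls back to the
#' siRNA-only assessment.
#'
#' @param edges data.frame from [build_network()]
#' @param called_sirnas data.frame from [call_nat_sirnas()]
#' @param profiles numeric matrix (transcripts x features) of per-gene
#'   modification profiles, e.g. from [gene_modification_profiles()]
#' @param sim_threshold absolute similarity threshold
#' @return edges with produces_nat_sirna, modification_similarity,
#'   feature_label
#' @export
annotate_features <- function(edges, called_sirnas, profiles,
                              sim_threshold = 0.8) {
  sirna_pairs <- if (nrow(called_sirnas)) {
    unique(unlist(strsplit(called_sirnas$source_pairs, ",")))
  } else character()
  edges$produces_nat_sirna <- edges$pair_id %in% sirna_pairs
  sim <- vapply(seq_len(nrow(edges)), function(k) {
    a <- edges$transcript_a[k]; b <- edges$transcript_b[k]
    if (!a %in% rownames(profiles) || !b %in% rownames(profiles)) {
      return(NA_real_)
    }
    va <- profiles[a, ]; vb <- profiles[b, ]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
    stats::cor(va, vb)
  }, numeric(1))
  edges$modification_similarity <- sim
  epi <- !is.na(sim) & abs(sim) >= sim_threshold
  edges$feature_label <- ifelse(edges$produces_nat_sirna & epi, "both",
    ifelse(edges$produces_nat_sirna, "siRNA",
      ifelse(epi, "epigenetic", "none")))
  edges
}

#' Per-gene modification profiles for edge annotation
#'
#' Concatenates, over the six marks, the binary domain-overlap profile of
#' each gene body split into `body_bins` bins (1 if the mark's domains
#' cover any part of the bin).
#'
#' @param catalog transcript data.frame
#' @param domains data.frame from [tiles_to_domains()]
#' @param body_bins bins per mark
#' @return numeric matrix, rownames = transcript ids
#' @export
gene_modification_profiles <- function(catalog, domains, body_bins = 10) {
  marks <- c(G1_MARKS, G2_MARKS)
  prof <- matrix(0, nrow = nrow(catalog), ncol = body_bins * length(marks),
                 dimnames = list(catalog$transcript_id, NULL))
  for (i in seq_len(nrow(catalog))) {
    g <- catalog[i, ]
    edges_ <- g$start + (g$end - g$start) * (0:body_bins) / body_bins
    for (m in seq_along(marks)) {
      d <- domains[domains$chrom == g$chrom & domains$mark == marks[m], ,
                   drop = FALSE]
      v <- vapply(seq_len(body_bins), function(b) {
        as.numeric(any(overlap_width(edges_[b], edges_[b + 1],
                                     d$start, d$end) > 0))
      }, numeric(1))
      if (g$strand == "-") v <- rev(v)
      prof[i, (m - 1) * body_bins + seq_len(body_bins)] <- v
    }
  }
  prof
}

#' Export the network
#'
#' Writes an edge-list TSV and a GraphML file (nodes attributed with
#' biotype and degree, edges with NAT type, PCC and feature label).
#'
#' @param edges annotated edge data.frame (rows with `edge == TRUE` are
#'   exported)
#' @param catalog transcript data.frame (biotype lookup)
#' @param path_tsv,path_graphml output paths (NULL skips either)
#' @return the igraph object, invisibly
#' @export
export_network <- function(edges, catalog, path_tsv = NULL,
                           path_graphml = NULL) {
  e <- edges[edges$edge, , drop = FALSE]
  cols <- intersect(c("transcript_a", "transcript_b", "nat_type", "pcc",
                      "pair_id", "feature_label"), names(e))
  g <- igraph::graph_from_data_frame(e[cols], directed = FALSE)
  igraph::V(g)$biotype <-
    catalog$biotype[match(igraph::V(g)$name, catalog$transcript_id)]
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(path_tsv)) write_tsv(e, path_tsv)
  if (!is.null(path_graphml)) {
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(g)
}
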