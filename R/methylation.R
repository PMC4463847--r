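#' Binned absolute methylation level of a gene region
#'
#' Divides the region (gene body, or the promoter upstream of the TSS) into
#' `n_bins` equal bins oriented 5' to 3', and computes per bin the pooled
#' absolute methylation level: total methylated reads over total coverage
#' across cytosines of the requested context (both DNA strands combined).
#' Bins containing no cytosine covered at `min_coverage` or more are
#' missing (NA), not zero.
#'
#' @param gene single-row transcript data.frame
#' @param sites methylation data.frame from [read_methylation_table()]
#' @param region `"body"` or `"promoter"`
#' @param context `"CG"`, `"CHG"` or `"CHH"`
#' @param n_bins number of bins
#' @param min_coverage minimum per-site total coverage for a site to count
#' @param promoter_length promoter extent upstream of the TSS (nt)
#' @return numeric vector of length `n_bins` (levels in [0,1] or NA),
#'   bin 1 = 5' end
#' @export
region_methylation <- function(gene, sites, region = c("body", "promoter"),
                               context = c("CG", "CHG", "CHH"), n_bins = 20,
                               min_coverage = 1, promoter_length = 1000) {
  region <- match.arg(region)
  context <- match.arg(context)
  stopifnot(nrow(gene) == 1)
  if (region == "body") {
    rs <- gene$start; re <- gene$end
  } else if (gene$strand == "+") {
    rs <- gene$start - promoter_length; re <- gene$start
  } else {
    rs <- gene$end; re <- gene$end + promoter_length
  }
  s <- sites[sites$chrom == gene$chrom & sites$context == context &
               sites$pos >= rs & sites$pos < re &
               sites$total >= min_coverage, , drop = FALSE]
  levels <- rep(NA_real_, n_bins)
  if (nrow(s)) {
    bin <- pmin(floor((s$pos - rs) / ((re - rs) / n_bins)) + 1L, n_bins)
    meth <- tapply(s$methylated, bin, sum)
    tot <- tapply(s$total, bin, sum)
    levels[as.integer(names(meth))] <- meth / tot
  }
  if (gene$strand == "-") levels <- rev(levels)
  levels
}

# level matrix (genes x bins) for a whole catalog
region_methylation_matrix <- function(catalog, sites, region, context,
                                      n_bins = 20, min_coverage = 1,
                                      promoter_length = 1000) {
  m <- t(vapply(seq_len(nrow(catalog)), function(i) {
    region_methylation(catalog[i, ], sites, region, context, n_bins,
                       min_coverage, promoter_length)
  }, numeric(n_bins)))
  rownames(m) <- catalog$transcript_id
  m
}

#' Pairwise DNA-methylation distance D_mC
#'
#' `D_mC = 1 - r`, where `r` is the Pearson correlation of the two genes'
#' binned methylation-level vectors over mutually covered bins.  A smaller
#' distance means a more similar methylation pattern.  Undefined (NA, with
#' a reason) when fewer than 3 bins are co-covered or either vector has
#' zero variance.
#'
#' @param levels_a,levels_b binned level vectors from [region_methylation()]
#' @return list: r, d_mc, n_bins_used, reason (NA when defined)
#' @export
dmc <- function(levels_a, levels_b) {
  ok <- !is.na(levels_a) & !is.na(levels_b)
  if (sum(ok) < 3) {
    return(list(r = NA_real_, d_mc = NA_real_, n_bins_used = sum(ok),
                reason = "fewer than 3 co-covered bins"))
  }
  a <- levels_a[ok]; b <- levels_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, d_mc = NA_real_, n_bins_used = sum(ok),
                reason = "zero variance"))
  }
  r <- stats::cor(a, b)
  list(r = r, d_mc = 1 - r, n_bins_used = sum(ok), reason = NA_character_)
}

# D_mC for every pair in a pair table, given a level matrix
pair_dmc <- function(pairs, level_matrix) {
  vapply(seq_len(nrow(pairs)), function(k) {
    dmc(level_matrix[pairs$transcript_a[k], ],
        level_matrix[pairs$transcript_b[k], ])$d_mc
  }, numeric(1))
}

#' Compare observed pair D_mC against randomized non-NAT pairs
#'
#' For each region x context combination, computes D_mC for the observed
#' pairs and for `repeats` randomized pairs drawn from the non-NAT pool,
#' then tests whether the observed distances are stochastically smaller
#' (one-tailed Wilcoxon rank-sum).  Deterministic given `seed`.
#'
#' @param pairs pair data.frame (transcript_a/transcript_b)
#' @param pool_catalog transcript data.frame of non-NAT genes
#' @param catalog transcript data.frame covering the pair members
#' @param sites methylation data.frame
#' @param repeats number of randomized pairs
#' @param seed RNG seed
#' @param n_bins,min_coverage,promoter_length passed to
#'   [region_methylation()]
#' @return data.frame: region, context, n_observed, mean_observed,
#'   mean_null, wilcoxon_p
#' @export
dmc_null_comparison <- function(pairs, pool_catalog, catalog, sites,
                                repeats = 10000, seed = 1, n_bins = 20,
                                min_coverage = 1, promoter_length = 1000) {
  if (nrow(pool_catalog) < 4) stop("non-NAT pool too small")
  set.seed(seed)
  out <- list()
  members <- catalog[catalog$transcript_id %in%
                       c(pairs$transcript_a, pairs$transcript_b), ,
                     drop = FALSE]
  for (region in c("promoter", "body")) {
    for (context in c("CG", "CHG", "CHH")) {
      lm_obs <- region_methylation_matrix(members, sites, region, context,
                                          n_bins, min_coverage,
                                          promoter_length)
      lm_pool <- region_methylation_matrix(pool_catalog, sites, region,
                                           context, n_bins, min_coverage,
                                           promoter_length)
      obs <- pair_dmc(pairs, lm_obs)
      ia <- sample.int(nrow(lm_pool), repeats, replace = TRUE)
      ib <- sample.int(nrow(lm_pool) - 1, repeats, replace = TRUE)
      ib <- ifelse(ib >= ia, ib + 1L, ib)  # distinct genes within a pair
      null <- vapply(seq_len(repeats), function(r) {
        dmc(lm_pool[ia[r], ], lm_pool[ib[r], ])$d_mc
      }, numeric(1))
      obs <- obs[!is.na(obs)]; null <- null[!is.na(null)]
      p <- if (length(obs) >= 3 && length(null) >= 3) {
        stats::wilcox.test(obs, null, alternative = "less",
                           exact = FALSE)$p.value
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        region = region, context = context, n_observed = length(obs),
        mean_observed = mean(obs), mean_null = mean(null), wilcoxon_p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare methylation distance between cis- and trans-NAT pairs
#'
#' Mean D_mC per group for each region x context combination ("-P" =
#' promoter, "-B" = body), with the difference and a rank-sum p-value.
#'
#' @param cis_dmc,trans_dmc data.frames with columns region, context, d_mc
#'   (one row per pair per combination)
#' @return data.frame: region, context, label, mean_cis, mean_trans,
#'   difference, wilcoxon_p (NA when either side is empty or degenerate)
#' @export
compare_cis_trans_distance <- function(cis_dmc, trans_dmc) {
  stopifnot(nrow(cis_dmc) > 0, nrow(trans_dmc) > 0)
  out <- list()
  for (region in c("promoter", "body")) {
    for (context in c("CG", "CHG", "CHH")) {
      a <- cis_dmc$d_mc[cis_dmc$region == region & cis_dmc$context == context]
      b <- trans_dmc$d_mc[trans_dmc$region == region &
                            trans_dmc$context == context]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      p <- if (length(a) >= 2 && length(b) >= 2) {
        stats::wilcox.test(a, b, exact = FALSE)$p.value
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        region = region, context = context,
        label = paste0(context, if (region == "promoter") "-P" else "-B"),
        mean_cis = if (length(a)) mean(a) else NA_real_,
        mean_trans = if (length(b)) mean(b) else NA_real_,
        difference = if (length(a) && length(b)) mean(b) - mean(a) else NA_real_,
        wilcoxon_p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
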