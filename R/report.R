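#' Percentage of a count over a total, at printed precision
#'
#' The reporting convention used throughout the package's summary tables:
#' `100 * numerator / denominator`, rounded to `digits` decimal places.
#'
#' @param numerator,denominator counts
#' @param digits decimal places (default 1, the precision genome-scale NAT
#'   surveys print)
#' @return numeric percentage
#' @export
percentage <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round(100 * numerator / denominator, digits)
}

#' Reference counts from the published genome-wide NAT survey of
#' A. thaliana
#'
#' Printed counts from the genome-wide natural-antisense-transcript survey
#' of the Arabidopsis TAIR10 annotation, used by the reporting utilities
#' and as worked examples for [percentage()]: gene and pair totals, the
#' biotype composition of the cis-, trans- and non-NAT gene groups, and the
#' histone pair-pattern counts.
#'
#' @return a named list of counts
#' @export
arabidopsis_nat_counts <- function() {
  list(
    total_genes = 33323,
    nat_genes = 7962,
    predicted_lncrna = 1138,
    nat_lncrna = 828,
    cis_pairs = 4080,
    cis_convergent = 1616,
    cis_containing = 811,
    cis_divergent = 384,
    cis_nearby = 1269,
    trans_pairs = 2491,
    trans_genes = 1788,
    trans_te_genes = 653,
    trans_other_npc_genes = 531,
    cis_genes = 7473,
    cis_te_genes = 205,
    cis_lncrna_genes = 821,
    cis_nonnearby_pairs_with_states = 2811,
    cis_g1_g1_pairs = 1904,
    cis_g1_g1_convergent = 1141,
    trans_g1_g1_pairs = 199,
    trans_g1_g2_pairs = 66,
    trans_g2_g2_pairs = 1239)
}

#' Headline percentages of the reference survey
#'
#' Recomputes, via [percentage()], the headline ratios of the reference
#' A. thaliana NAT survey from its printed counts: the share of annotated
#' genes in NAT pairs, of predicted lncRNAs participating in NATs, the
#' biotype composition of the trans- and cis-NAT gene groups, and the
#' G1/G2 histone pair-pattern shares.
#'
#' @return named numeric vector of percentages
#' @export
nat_reference_percentages <- function() {
  k <- arabidopsis_nat_counts()
  c(pct_nat_genes = percentage(k$nat_genes, k$total_genes),
    pct_lncrna_in_nats = percentage(k$nat_lncrna, k$predicted_lncrna),
    pct_npc_in_trans_genes = percentage(
      k$trans_te_genes + k$trans_other_npc_genes, k$trans_genes),
    pct_te_in_trans_genes = percentage(k$trans_te_genes, k$trans_genes),
    pct_other_npc_in_trans_genes = percentage(k$trans_other_npc_genes,
                                              k$trans_genes),
    pct_cis_g1_g1 = percentage(k$cis_g1_g1_pairs,
                               k$cis_nonnearby_pairs_with_states),
    pct_g1_g1_in_convergent = percentage(k$cis_g1_g1_convergent,
                                         k$cis_convergent),
    pct_trans_g1_g1 = percentage(k$trans_g1_g1_pairs, k$trans_pairs),
    pct_trans_g1_g2 = percentage(k$trans_g1_g2_pairs, k$trans_pairs),
    pct_te_in_cis_genes = percentage(k$cis_te_genes, k$cis_genes))
}
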