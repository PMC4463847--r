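site_df <- function(pos, methylated, total = 10, context = "CG",
                    chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             methylated = methylated, total = total, stringsAsFactors = FALSE)
}

test_that("bin levels pool counts and orient 5' to 3'", {
  gene <- toy_catalog(list(id = "g.1", start = 0, end = 200, strand = "+"))
  # fully methylated sites -> every covered bin at 1.0
  s_full <- site_df(seq(5, 195, by = 10), methylated = 10)
  lv <- region_methylation(gene[1, ], s_full, "body", "CG", n_bins = 10)
  expect_equal(lv, rep(1, 10))

  # two sites in one bin pool to (3+1)/(10+10), not the mean of ratios
  s_pool <- site_df(c(2, 8), methylated = c(3, 1))
  lv2 <- region_methylation(gene[1, ], s_pool, "body", "CG", n_bins = 10)
  expect_equal(lv2[1], 0.2)
  expect_true(all(is.na(lv2[-1])))

  # context filter: CHH sites do not contribute to CG levels
  lv3 <- region_methylation(gene[1, ], site_df(5, 5, context = "CHH"),
                            "body", "CG", n_bins = 10)
  expect_true(all(is.na(lv3)))

  # minus-strand gene: bin 1 is the 3' side of the genomic axis
  gene_m <- toy_catalog(list(id = "g.1", start = 0, end = 200, strand = "-"))
  s_grad <- site_df(c(5, 195), methylated = c(0, 10))
  lv_p <- region_methylation(gene[1, ], s_grad, "body", "CG", n_bins = 10)
  lv_m <- region_methylation(gene_m[1, ], s_grad, "body", "CG", n_bins = 10)
  expect_equal(lv_m, rev(lv_p))
})

test_that("promoter bins sit upstream of the TSS, strand-aware", {
  gene_p <- toy_catalog(list(id = "g.1", start = 2000, end = 3000,
                             strand = "+"))
  gene_m <- toy_catalog(list(id = "g.1", start = 2000, end = 3000,
                             strand = "-"))
  s <- site_df(c(1500, 3500), methylated = c(10, 0))
  lv_p <- region_methylation(gene_p[1, ], s, "promoter", "CG", n_bins = 2,
                             promoter_length = 1000)
  lv_m <- region_methylation(gene_m[1, ], s, "promoter", "CG", n_bins = 2,
                             promoter_length = 1000)
  expect_equal(lv_p, c(NA, 1))  # site at 1500 in the bin nearest the TSS
  # for '-' the promoter lies above the gene end and bin 1 is its far
  # (5'-most) side, which holds the site at 3500
  expect_equal(lv_m, c(0, NA))
})

test_that("bin levels equal brute-force per-cytosine aggregation", {
  set.seed(77)
  for (i in 1:50) {
    gs <- sample(0:5000, 1); glen <- sample(100:2000, 1)
    gene <- toy_catalog(list(id = "g.1", start = gs, end = gs + glen,
                             strand = sample(c("+", "-"), 1)))
    pos <- sort(sample(seq(gs, gs + glen - 1), sample(5:40, 1)))
    s <- site_df(pos, methylated = sample(0:10, length(pos), replace = TRUE))
    n_bins <- sample(3:10, 1)
    got <- region_methylation(gene[1, ], s, "body", "CG", n_bins = n_bins)
    oracle <- rep(NA_real_, n_bins)
    for (b in seq_len(n_bins)) {
      lo <- gs + glen * (b - 1) / n_bins; hi <- gs + glen * b / n_bins
      inb <- s$pos >= lo & s$pos < hi
      if (b == n_bins) inb <- s$pos >= lo & s$pos < gs + glen
      if (any(inb)) oracle[b] <- sum(s$methylated[inb]) / sum(s$total[inb])
    }
    if (gene$strand == "-") oracle <- rev(oracle)
    expect_equal(got, oracle)
  }
})

test_that("D_mC is one minus Pearson r, with degenerate cases flagged", {
  v <- c(0.1, 0.5, 0.9, 0.3, 0.7)
  expect_equal(dmc(v, v)$d_mc, 0)
  expect_equal(dmc(v, 1 - v)$d_mc, 2)

  set.seed(88)
  for (i in 1:100) {
    a <- runif(10); b <- runif(10)
    res <- dmc(a, b)
    expect_equal(res$d_mc, 1 - cor(a, b))
    expect_equal(res$d_mc, dmc(b, a)$d_mc)  # symmetry
    expect_true(res$d_mc >= 0 && res$d_mc <= 2)
  }

  few <- dmc(c(0.1, NA, NA, 0.4, NA), c(0.2, 0.3, NA, 0.5, NA))
  expect_true(is.na(few$d_mc))
  expect_match(few$reason, "co-covered")
  flat <- dmc(rep(0.5, 5), runif(5))
  expect_true(is.na(flat$d_mc))
  expect_match(flat$reason, "variance")
})

test_that("a single-bin level equals the pooled gene-wide level", {
  gene <- toy_catalog(list(id = "g.1", start = 0, end = 300, strand = "+"))
  s <- site_df(c(10, 150, 290), methylated = c(2, 5, 9))
  lv <- region_methylation(gene[1, ], s, "body", "CG", n_bins = 1)
  expect_equal(lv, sum(c(2, 5, 9)) / 30)
})

test_that("pair-concordant methylation beats the randomized null", {
  b <- small_bundle()
  tx <- b$catalog$transcripts
  cis <- find_cis_pairs(tx)
  pairs <- cis[!is.na(cis$overlap_start), ]
  non_nat <- tx[!tx$transcript_id %in% c(b$truth$transcript_a,
                                         b$truth$transcript_b), ]
  cmp <- dmc_null_comparison(pairs, non_nat, tx, b$methylation,
                             repeats = 400, seed = 5)
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$wilcoxon_p < 0.05))
  expect_true(all(cmp$mean_observed < cmp$mean_null))

  # determinism under the seed
  cmp2 <- dmc_null_comparison(pairs, non_nat, tx, b$methylation,
                              repeats = 400, seed = 5)
  expect_identical(cmp, cmp2)
  expect_error(dmc_null_comparison(pairs, non_nat[1:2, ], tx,
                                   b$methylation),
               "pool")
})

test_that("cis/trans distance comparison reports all six combinations", {
  mk <- function(vals) {
    expand.grid(region = c("promoter", "body"),
                context = c("CG", "CHG", "CHH"),
                rep = 1:5, stringsAsFactors = FALSE) |>
      transform(d_mc = vals)
  }
  set.seed(3)
  same <- mk(runif(30))
  res <- compare_cis_trans_distance(same, same)
  expect_equal(nrow(res), 6)
  expect_equal(res$difference, rep(0, 6))
  expect_setequal(res$label, c("CG-P", "CHG-P", "CHH-P", "CG-B", "CHG-B",
                               "CHH-B"))

  # planted direction: trans less concordant in the body
  cis_d <- mk(runif(30, 0, 0.4))
  trans_d <- mk(runif(30, 0.8, 1.2))
  res2 <- compare_cis_trans_distance(cis_d, trans_d)
  body <- res2[res2$region == "body", ]
  expect_true(all(body$difference > 0))
  expect_true(all(body$wilcoxon_p < 0.05))

  # an absent context is flagged missing, not zero
  no_chh <- cis_d[cis_d$context != "CHH", ]
  res3 <- compare_cis_trans_distance(no_chh, trans_d)
  expect_true(all(is.na(res3$mean_cis[res3$context == "CHH"])))
})
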