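# one convergent pair: + [0,1000), - [900,2000); overlap [900,1000), L_o=100,
# non-overlap union length 1900
density_fixture <- function() {
  catalog <- toy_catalog(
    list(id = "tA.1", start = 0, end = 1000, strand = "+"),
    list(id = "tB.1", start = 900, end = 2000, strand = "-"))
  pairs <- find_cis_pairs(catalog)
  list(catalog = catalog, pair = pairs[1, ])
}

lib_at <- function(starts, len = 20, dataset = "D1") {
  do.call(rbind, lapply(seq_along(starts), function(i) {
    data.frame(read_id = sprintf("r%03d", i),
               sequence = paste0(strrep("A", len - 3), sprintf("%03d", i)),
               length = len, chrom = "chr1", start = starts[i],
               end = starts[i] + len, strand = "+", dataset_id = dataset,
               count = 1, stringsAsFactors = FALSE)
  }))
}

test_that("pair densities follow the N/L definitions", {
  fx <- density_fixture()
  # 10 distinct loci inside the overlap, 5 in the non-overlap gene regions
  lib <- lib_at(c(seq(900, 972, by = 8), seq(100, 500, by = 100)))
  d <- pair_densities(fx$pair, lib, fx$catalog, dataset = "D1")
  expect_equal(d$N_o, 10); expect_equal(d$L_o, 100)
  expect_equal(d$N_g, 5); expect_equal(d$L_g, 1900)
  expect_equal(d$density_o, 0.1)
  expect_equal(d$density_g, 5 / 1900)

  # no small RNA anywhere
  d0 <- pair_densities(fx$pair, lib[0, ], fx$catalog)
  expect_equal(c(d0$density_o, d0$density_g), c(0, 0))

  # a locus straddling the overlap boundary is not contained in it
  d1 <- pair_densities(fx$pair, lib_at(890), fx$catalog)
  expect_equal(d1$N_o, 0)
  expect_equal(d1$N_g, 0)  # nor fully inside the non-overlap union piece
})

test_that("density counts equal a brute-force membership test", {
  set.seed(33)
  b <- small_bundle()
  tx <- b$catalog$transcripts
  pairs <- find_cis_pairs(tx)
  pairs <- pairs[!is.na(pairs$overlap_start), ]
  lib <- build_library(b$smrna, b$exclusion)$library
  for (k in sample(nrow(pairs), min(8, nrow(pairs)))) {
    p <- pairs[k, ]
    d <- pair_densities(p, lib, tx, dataset = "D1")
    members <- tx[match(c(p$transcript_a, p$transcript_b), tx$transcript_id), ]
    loci <- unique(lib[lib$dataset_id == "D1",
                       c("sequence", "chrom", "start", "end")])
    in_ov <- loci$chrom == p$chrom & loci$start >= p$overlap_start &
      loci$end <= p$overlap_end
    in_gene <- rep(FALSE, nrow(loci))
    for (m in 1:2) {
      in_gene <- in_gene | (loci$chrom == members$chrom[m] &
                              loci$start >= members$start[m] &
                              loci$end <= members$end[m])
    }
    expect_equal(d$N_o, sum(in_ov))
    expect_equal(d$N_g, sum(in_gene & !in_ov &
                              !(loci$start < p$overlap_end &
                                  loci$end > p$overlap_start &
                                  loci$chrom == p$chrom)))
  }
})

test_that("enrichment score and one-tailed paired t match closed forms", {
  fx <- density_fixture()
  expect_error(enrichment_test(fx$pair, lib_at(900), fx$catalog),
               "insufficient")

  # identical per-pair densities: exact null identity
  catalog <- toy_catalog(
    list(id = "tA.1", start = 0, end = 1000, strand = "+"),
    list(id = "tB.1", start = 900, end = 2000, strand = "-"),
    list(id = "tC.1", start = 5000, end = 6000, strand = "+"),
    list(id = "tD.1", start = 5900, end = 7000, strand = "-"))
  pairs <- find_cis_pairs(catalog)
  # per pair: 1 locus in the 100-nt overlap (0.01) and 19 loci in the
  # 1900-nt non-overlap regions (also 0.01)
  lib <- lib_at(c(910, seq(0, 720, by = 40), 5910, seq(5000, 5720, by = 40)))
  res <- enrichment_test(pairs, lib, catalog)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 0.5)
  expect_equal(res$R, 1)

  # hand-worked three-pair example against the closed-form paired t
  d_o <- c(0.1, 0.2, 0.15); d_g <- c(0.005, 0.01, 0.02)
  diffs <- d_o - d_g
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(3))
  p_hand <- stats::pt(t_hand, df = 2, lower.tail = FALSE)
  got <- natscape:::paired_t_greater(d_o, d_g)
  expect_equal(got$t, t_hand)
  expect_equal(got$p, p_hand)
})

test_that("doubling all densities leaves the enrichment score unchanged", {
  d_o <- c(0.1, 0.2, 0.15); d_g <- c(0.005, 0.01, 0.02)
  expect_equal(mean(2 * d_o) / mean(2 * d_g), mean(d_o) / mean(d_g))
})

test_that("p-values fall as the planted rate ratio grows", {
  p1 <- median(enrichment_calibration(40, 30, 0.01, 0.01, seed = 5))
  p2 <- median(enrichment_calibration(40, 30, 0.02, 0.01, seed = 5))
  p5 <- median(enrichment_calibration(40, 30, 0.05, 0.01, seed = 5))
  expect_true(p5 < p2 && p2 < p1)
})

test_that("the enrichment table is laid out per data set and stratum", {
  b <- small_bundle()
  tx <- b$catalog$transcripts
  cis <- find_cis_pairs(tx)
  pairs <- cis[!is.na(cis$overlap_start), ]
  lib <- build_library(b$smrna, b$exclusion)$library
  tab <- enrichment_table(pairs, lib, tx, datasets = c("D1", "D2"))
  expect_equal(nrow(tab), 2 * 9)
  all_cis <- tab[tab$stratum == "all_cis" & tab$dataset_id == "D1", ]
  expect_gt(all_cis$R, 2)  # planted 6x rate ratio
  expect_lt(all_cis$p_value, 0.01)
})

test_that("dsRNA coverage check compares overlap with equal-length flanks", {
  fx <- density_fixture()
  # uniform coverage: one read spanning everything -> ratio 1, p at null
  cov_u <- data.frame(chrom = "chr1", start = 0, end = 2000)
  res_u <- dsrna_overlap_check(fx$pair, cov_u, fx$catalog)
  expect_equal(res_u$per_pair$ratio, 1)

  # overlap covered 10 deep, flanks 2 deep -> ratio 5
  cov <- rbind(
    do.call(rbind, replicate(10, data.frame(chrom = "chr1", start = 900,
                                            end = 1000), simplify = FALSE)),
    do.call(rbind, replicate(2, data.frame(chrom = "chr1", start = 800,
                                           end = 900), simplify = FALSE)),
    do.call(rbind, replicate(2, data.frame(chrom = "chr1", start = 1000,
                                           end = 1100), simplify = FALSE)))
  res <- dsrna_overlap_check(fx$pair, cov, fx$catalog)
  expect_equal(res$per_pair$cov_overlap, 10)
  expect_equal(res$per_pair$cov_flank, 2)
  expect_equal(res$per_pair$ratio, 5)
})
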