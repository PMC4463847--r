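iv <- function(start, end, strand, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("orientation subtypes follow strand geometry", {
  # + [100,500) meets - [400,800): tails overlap
  expect_equal(classify_orientation(iv(100, 500, "+"), iv(400, 800, "-")),
               "convergent")
  # mirrored: heads overlap
  expect_equal(classify_orientation(iv(400, 800, "+"), iv(100, 500, "-")),
               "divergent")
  # nesting wins
  expect_equal(classify_orientation(iv(100, 1000, "+"), iv(300, 600, "-")),
               "containing")
  # equal spans are mutual full overlap
  expect_equal(classify_orientation(iv(100, 500, "+"), iv(100, 500, "-")),
               "containing")
  # minimal 1-nt overlap at the + gene's end
  expect_equal(classify_orientation(iv(100, 500, "+"), iv(499, 900, "-")),
               "convergent")
  # no overlap, 3' ends face across the gap
  expect_equal(classify_orientation(iv(100, 500, "+"), iv(550, 900, "-")),
               "nearby_tail_to_tail")
  expect_equal(classify_orientation(iv(550, 900, "+"), iv(100, 500, "-")),
               "nearby_head_to_head")
  expect_error(classify_orientation(iv(1, 10, "+"), iv(5, 20, "+")),
               "same-strand")
})

test_that("classification agrees with the brute-force predicate oracle", {
  set.seed(202)
  for (i in 1:2000) {
    s1 <- sample(0:5000, 1); l1 <- sample(50:2000, 1)
    # keep the second interval close enough to interact
    s2 <- max(0, s1 + sample(-2200:2200, 1)); l2 <- sample(50:2000, 1)
    a <- iv(s1, s1 + l1, "+"); b <- iv(s2, s2 + l2, "-")
    expected <- brute_force_subtype(a, b)
    if (is.na(expected)) next  # out of nearby range: not a pair
    expect_equal(classify_orientation(a, b), expected,
                 label = sprintf("[%d,%d)+ vs [%d,%d)-", s1, s1 + l1, s2,
                                 s2 + l2))
  }
})

test_that("pair finding emits each qualifying pair once, canonically", {
  catalog <- toy_catalog(
    list(id = "tA.1", start = 100, end = 500, strand = "+"),
    list(id = "tB.1", start = 400, end = 800, strand = "-"),
    list(id = "tC.1", start = 850, end = 920, strand = "+"),   # gap 50 to tB
    list(id = "tD.1", start = 950, end = 1200, strand = "+"),  # same strand as C
    list(id = "tE.1", start = 3000, end = 3500, strand = "-", biotype = "TE"))
  pairs <- find_cis_pairs(catalog)
  expect_equal(nrow(pairs), 2)
  expect_true(all(pairs$transcript_a < pairs$transcript_b))
  conv <- pairs[pairs$subtype == "convergent", ]
  expect_equal(conv$overlap_start, 400)
  expect_equal(conv$overlap_end, 500)
  expect_equal(conv$coding_class, "PC/PC")
  nb <- pairs[grepl("nearby", pairs$subtype), ]
  expect_equal(nb$subtype, "nearby_head_to_head")
  expect_equal(nb$gap, 50)
  expect_true(is.na(nb$overlap_start))

  # catalog order does not change the canonical output
  shuffled <- find_cis_pairs(catalog[c(4, 2, 5, 1, 3), ])
  expect_equal(shuffled[order(shuffled$pair_id), -1],
               pairs[order(pairs$pair_id), -1], ignore_attr = TRUE)

  # same-strand overlaps are never emitted; empty catalog gives empty output
  expect_false(any(paste(pairs$transcript_a, pairs$transcript_b) ==
                     "tC.1 tD.1"))
  expect_equal(nrow(find_cis_pairs(catalog[0, ])), 0)
})

test_that("nearby pairs respect the configurable gap cutoff", {
  catalog <- toy_catalog(
    list(id = "tA.1", start = 100, end = 500, strand = "+"),
    list(id = "tB.1", start = 650, end = 900, strand = "-"))  # gap 150
  expect_equal(nrow(find_cis_pairs(catalog, nearby_max_gap = 100)), 0)
  p <- find_cis_pairs(catalog, nearby_max_gap = 150)
  expect_equal(p$subtype, "nearby_tail_to_tail")
  expect_equal(p$gap, 150)
})

test_that("every emitted overlap lies inside both spans", {
  b <- small_bundle()
  cis <- find_cis_pairs(b$catalog$transcripts)
  tx <- b$catalog$transcripts
  ov <- cis[!is.na(cis$overlap_start), ]
  for (k in seq_len(nrow(ov))) {
    a <- tx[match(ov$transcript_a[k], tx$transcript_id), ]
    bb <- tx[match(ov$transcript_b[k], tx$transcript_id), ]
    expect_true(ov$overlap_start[k] >= max(a$start, bb$start))
    expect_true(ov$overlap_end[k] <= min(a$end, bb$end))
    expect_true(a$strand != bb$strand)
  }
})

test_that("overlap position is labelled relative to the CDS", {
  catalog <- toy_catalog(
    list(id = "tA.1", start = 0, end = 1000, strand = "+"),
    list(id = "tB.1", start = 850, end = 1400, strand = "-",
         biotype = "lncRNA"))
  catalog$cds_start[1] <- 200
  catalog$cds_end[1] <- 800
  pairs <- find_cis_pairs(catalog)
  pos <- classify_overlap_position(pairs, catalog)
  expect_equal(pos$position[pos$transcript_id == "tA.1"], "3'-UTR")

  # upstream overlap on the same gene
  catalog2 <- toy_catalog(
    list(id = "tA.1", start = 0, end = 1000, strand = "+"),
    list(id = "tB.1", start = 0, end = 150, strand = "-",
         biotype = "lncRNA"))
  catalog2$cds_start[1] <- 200
  catalog2$cds_end[1] <- 800
  pos2 <- classify_overlap_position(find_cis_pairs(catalog2), catalog2)
  expect_equal(pos2$position[pos2$transcript_id == "tA.1"], "5'-UTR")

  # overlap spanning both CDS boundaries
  catalog3 <- toy_catalog(
    list(id = "tA.1", start = 0, end = 1000, strand = "+"),
    list(id = "tB.1", start = 100, end = 900, strand = "-",
         biotype = "lncRNA"))
  catalog3$cds_start[1] <- 200
  catalog3$cds_end[1] <- 800
  pos3 <- classify_overlap_position(find_cis_pairs(catalog3), catalog3)
  expect_equal(pos3$position[pos3$transcript_id == "tA.1"], "across-CDS")

  # PC member without CDS annotation is labelled unknown with a warning
  catalog4 <- catalog
  catalog4$cds_start[1] <- NA
  expect_warning(pos4 <- classify_overlap_position(find_cis_pairs(catalog4),
                                                   catalog4),
                 "without CDS")
  expect_equal(pos4$position[pos4$transcript_id == "tA.1"], "unknown")
})
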