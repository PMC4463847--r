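tiles_df <- function(starts, ends, mark = "H3K4me3", chrom = "chr1") {
  data.frame(chrom = chrom, start = starts, end = ends, mark = mark,
             stringsAsFactors = FALSE)
}

test_that("tile joining honours the 200-nt gap and 400-nt minimum", {
  # gap of exactly 200 merges; the 600-nt result is kept
  d <- tiles_to_domains(tiles_df(c(0, 400), c(200, 600)))
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(0, 600))

  # a lone 300-nt tile is below the domain minimum
  expect_equal(nrow(tiles_to_domains(tiles_df(0, 300))), 0)

  # a 400-nt merged interval is kept (boundary inclusive)
  d400 <- tiles_to_domains(tiles_df(c(0, 250), c(150, 400)))
  expect_equal(c(d400$start, d400$end), c(0, 400))

  # gap of 201 leaves two fragments, both under 400 nt
  expect_equal(nrow(tiles_to_domains(tiles_df(c(0, 401), c(200, 601)))), 0)
})

test_that("tile joining is order-invariant and idempotent", {
  set.seed(55)
  t <- tiles_df(starts = seq(0, 5000, by = 350), ends = seq(0, 5000, 350) + 200)
  t <- rbind(t, tiles_df(c(10000, 10150), c(10100, 10600), mark = "H3K27me3"))
  d1 <- tiles_to_domains(t)
  d2 <- tiles_to_domains(t[sample(nrow(t)), ])
  expect_equal(d1, d2)
  expect_equal(tiles_to_domains(d1), d1)
})

test_that("gene states derive from G1/G2 mark overlap", {
  catalog <- toy_catalog(
    list(id = "g1.1", start = 0, end = 1000, strand = "+"),
    list(id = "both.1", start = 2000, end = 3000, strand = "+"),
    list(id = "non.1", start = 4000, end = 5000, strand = "+"),
    list(id = "g2.1", start = 6000, end = 7000, strand = "-"))
  domains <- data.frame(
    chrom = "chr1",
    start = c(500, 2000, 2100, 6500),
    end = c(1500, 2600, 2700, 7600),
    mark = c("H3K4me3", "H3K36me3", "H3K27me3", "H3K27me1"),
    stringsAsFactors = FALSE)
  st <- gene_mark_state(catalog, domains)
  expect_equal(st$group_state,
               c("G1", "G1+G2", "NON", "G2"))
  expect_error(gene_mark_state(catalog,
                               tiles_df(0, 500, mark = "H3K9me2")),
               "unknown mark")
})

test_that("metagene profile bins match a per-position average", {
  gene <- toy_catalog(list(id = "g.1", start = 2000, end = 3000, strand = "+"))
  domains <- tiles_df(1500, 3500)
  prof <- metagene_profile(gene, domains, body_bins = 10, flank = 1000,
                           flank_bin = 100)
  # domain covers the whole body and half of each flank
  expect_equal(prof[11:20], rep(1, 10), ignore_attr = TRUE)
  expect_equal(prof[1:10], c(rep(0, 5), rep(1, 5)), ignore_attr = TRUE)
  expect_equal(prof[21:30], c(rep(1, 5), rep(0, 5)), ignore_attr = TRUE)

  # a minus-strand gene gives the mirrored profile
  gene_m <- gene; gene_m$strand <- "-"
  dom_asym <- tiles_df(2000, 2300)  # 5'-biased on +, 3'-biased on -
  p_plus <- metagene_profile(gene, dom_asym, 10, 1000, 100)
  p_minus <- metagene_profile(gene_m, dom_asym, 10, 1000, 100)
  expect_equal(p_minus, rev(p_plus))

  # brute-force per-position oracle on random geometry (disjoint domains,
  # gene length a multiple of the bin count so bin edges are integers)
  set.seed(66)
  for (i in 1:20) {
    gs <- sample(2000:2400, 1); glen <- 5 * sample(40:300, 1)
    ds <- c(1000, 3000, 5000) + sample(0:500, 3)
    de <- ds + sample(100:800, 3)
    g <- toy_catalog(list(id = "g.1", start = gs, end = gs + glen,
                          strand = "+"))
    dd <- tiles_df(ds, de)
    got <- metagene_profile(g, dd, body_bins = 5, flank = 200, flank_bin = 50)
    covered_mean <- function(s, e) {
      pos <- seq(s, e - 1)
      mean(vapply(pos, function(p) any(dd$start <= p & p < dd$end),
                  logical(1)))
    }
    edges <- c(seq(gs - 200, gs, 50), gs + glen * (1:5) / 5,
               seq(gs + glen + 50, gs + glen + 200, 50))
    oracle <- vapply(seq_len(length(edges) - 1), function(b) {
      covered_mean(edges[b], edges[b + 1])
    }, numeric(1))
    expect_equal(got, oracle, ignore_attr = TRUE)
  }

  # genes shorter than the bin count are skipped with a warning
  tiny <- toy_catalog(list(id = "t.1", start = 0, end = 5, strand = "+"))
  expect_warning(metagene_profile(rbind(gene, tiny), domains, 10, 1000, 100),
                 "skipped")
})

test_that("sixteen ordered state combinations collapse to ten classes", {
  states <- c("G1", "G2", "G1+G2", "NON")
  combos <- expand.grid(a = states, b = states, stringsAsFactors = FALSE)
  cls <- natscape:::pair_pattern_class(combos$a, combos$b)
  expect_equal(sort(unique(cls)), sort(natscape:::PAIR_PATTERN_CLASSES))
  expect_equal(natscape:::pair_pattern_class("G1", "G2"),
               natscape:::pair_pattern_class("G2", "G1"))
  expect_equal(natscape:::pair_pattern_class("G1+G2", "NON"), "G1+G2_NON")
})

test_that("pair pattern percentages sum to 100 and drop stateless members", {
  pairs <- data.frame(pair_id = c("p1", "p2", "p3"),
                      transcript_a = c("a", "c", "e"),
                      transcript_b = c("b", "d", "missing"),
                      stringsAsFactors = FALSE)
  states <- data.frame(transcript_id = c("a", "b", "c", "d", "e"),
                       group_state = c("G1", "G2", "G2", "G1", "NON"),
                       stringsAsFactors = FALSE)
  res <- classify_pair_patterns(pairs, states)
  expect_equal(res$n_pairs, 2)
  expect_equal(res$n_dropped, 1)
  expect_equal(sum(res$percentages), 100)
  expect_equal(unname(res$percentages["G1_G2"]), 100)
})

test_that("randomized null matches degenerate and closed-form pools", {
  # all-G1 pool: every null pair is G1_G1 with zero variance
  null_g1 <- randomized_null(rep("G1", 40), n_pairs = 10, repeats = 200,
                             seed = 3)
  expect_equal(unname(null_g1$mean["G1_G1"]), 100)
  expect_equal(unname(null_g1$lower["G1_G1"]), 100)

  # determinism under the seed
  n1 <- randomized_null(rep(c("G1", "G2"), 50), 10, repeats = 100, seed = 9)
  n2 <- randomized_null(rep(c("G1", "G2"), 50), 10, repeats = 100, seed = 9)
  expect_identical(n1, n2)

  expect_error(randomized_null(rep("G1", 5), n_pairs = 10), "pool smaller")
})
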