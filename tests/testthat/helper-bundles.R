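# shared fixtures: bundles are generated once per test run and memoised

.bundle_cache <- new.env(parent = emptyenv())

cached_bundle <- function(name, config) {
  if (is.null(.bundle_cache[[name]])) {
    .bundle_cache[[name]] <- generate_bundle(config)
  }
  .bundle_cache[[name]]
}

# default small study bundle
small_bundle <- function() {
  cached_bundle("small", synth_config(seed = 42))
}

# tiny catalog builder for hand-constructed geometry tests
toy_catalog <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(transcript_id = r[["id"]], gene_id = sub("\\.\\d+$", "", r[["id"]]),
               chrom = r[["chrom"]] %||% "chr1",
               start = as.numeric(r[["start"]]), end = as.numeric(r[["end"]]),
               strand = r[["strand"]],
               biotype = r[["biotype"]] %||% "PC",
               stringsAsFactors = FALSE)
  }))
  df$coding_class <- ifelse(df$biotype == "PC", "PC", "NPC")
  df$cds_start <- NA_real_
  df$cds_end <- NA_real_
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force cis-subtype classifier: tests the overlap predicates literally
brute_force_subtype <- function(a, b, nearby_max_gap = 100) {
  plus <- if (a$strand == "+") a else b
  minus <- if (a$strand == "+") b else a
  ov_s <- max(plus$start, minus$start)
  ov_e <- min(plus$end, minus$end)
  if (ov_e > ov_s) {
    if ((plus$start <= minus$start && minus$end <= plus$end) ||
        (minus$start <= plus$start && plus$end <= minus$end)) {
      return("containing")
    }
    # + transcript 3' end (its `end`) inside the overlap => tails meet
    if (ov_s < plus$end && plus$end <= ov_e &&
        ov_s <= minus$start && minus$start < ov_e) {
      return("convergent")
    }
    # + transcript 5' end (its `start`) and - transcript 5' end (its `end`)
    if (ov_s <= plus$start && plus$start < ov_e &&
        ov_s < minus$end && minus$end <= ov_e) {
      return("divergent")
    }
    stop("unclassifiable overlap")
  }
  gap <- ov_s - ov_e
  if (gap > nearby_max_gap) return(NA_character_)
  if (plus$end <= minus$start) "nearby_tail_to_tail" else "nearby_head_to_head"
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
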