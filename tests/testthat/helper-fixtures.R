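# Fixture builders used across the suite. Everything is generated in code;
# dense_to_bedgraph deliberately uses base rle() so that tracks reaching the
# package go through its own bedGraph reader.

dense_to_bedgraph <- function(v, chrom, path) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                     format(r$values[keep], scientific = FALSE, trim = TRUE)),
             path)
  path
}

# build a coverage_track from dense per-base vectors via bedGraph files
make_track <- function(plus, minus = NULL, chrom = "chrT") {
  pf <- withr::local_tempfile(fileext = ".bedgraph",
                              .local_envir = parent.frame())
  dense_to_bedgraph(plus, chrom, pf)
  mf <- NULL
  if (!is.null(minus)) {
    stopifnot(length(minus) == length(plus))
    mf <- withr::local_tempfile(fileext = ".bedgraph",
                                .local_envir = parent.frame())
    dense_to_bedgraph(minus, chrom, mf)
  }
  read_bedgraph_pair(pf, mf, stats::setNames(length(plus), chrom))
}

one_gene <- function(start, end, strand, chrom = "chrT", id = "g1",
                     cls = "histone") {
  gene_table(id, chrom, start, end, strand, cls)
}

# fabricate a readthrough_result table from a vector of ratios
fake_results <- function(ratios, gene_class = "histone",
                         valid = rep(TRUE, length(ratios))) {
  data.frame(gene_id = sprintf("g%03d", seq_along(ratios)),
             gene_class = gene_class, statistic = "proseq",
             numerator = NA_real_, denominator = NA_real_, ratio = ratios,
             valid = valid,
             invalid_reason = ifelse(valid, "none", "zero_denominator"),
             stringsAsFactors = FALSE)
}

# brute-force per-base window sum in transcript coordinates: offsets
# [off_a, off_b) downstream of the anchor coordinate, one base at a time
naive_window_sum <- function(dense, anchor, strand, off_a, off_b) {
  tot <- 0
  for (d in off_a:(off_b - 1)) {
    pos <- if (strand == "+") anchor + d else anchor - 1 - d
    if (pos >= 0 && pos < length(dense)) tot <- tot + dense[pos + 1]
  }
  tot
}

# brute-force exclusive Venn region counts by per-element enumeration
naive_venn <- function(sets) {
  universe <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  res <- integer(nrow(combos))
  for (el in universe) {
    memb <- vapply(sets, function(s) el %in% s, TRUE)
    for (r in seq_len(nrow(combos))) {
      if (all(memb == unlist(combos[r, ]))) res[r] <- res[r] + 1L
    }
  }
  res
}

# build dual-library differential records and call them (shared by polya and
# acceptance tests)
run_polya_pipeline <- function(dual, thresholds = call_thresholds()) {
  grp <- rep(c("ctrl", "pert"), each = ncol(dual$polya) / 2)
  de_pa <- simple_differential(dual$polya, grp)
  de_rd <- simple_differential(dual$ribo, grp)
  recs <- rbind(
    data.frame(de_pa[c("transcript_id", "log2_fc", "fdr")],
               library_type = "polyA_selected"),
    data.frame(de_rd[c("transcript_id", "log2_fc", "fdr")],
               library_type = "ribo_depleted"))
  call_aberrant_polyadenylation(recs, thresholds)
}
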