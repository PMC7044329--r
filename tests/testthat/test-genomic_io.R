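test_that("BED records map to half-open intervals with optional fields", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tG1\t0\t+", "chr2\t5\t9"), path)
  iv <- read_bed(path)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(100, 5))
  expect_equal(iv$end, c(200, 9))
  expect_equal(iv$name, c("G1", NA))
  expect_equal(iv$strand, c("+", "."))
})

test_that("malformed BED lines are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tG1\t0\t+", "chr1\t200\t100\tG2\t0\t+"), path)
  expect_error(read_bed(path), "line 2.*start > end")
  writeLines(c("chr1\t1.5\t7"), path)
  expect_error(read_bed(path), "line 1.*non-integer")
  writeLines(c("chr1\t10"), path)
  expect_error(read_bed(path), "line 1.*fewer than 3")
  expect_error(read_bed(file.path(tempdir(), "nope.bed")), "not found")
})

test_that("BED round trip preserves records", {
  path <- withr::local_tempfile(fileext = ".bed")
  lines <- c("chr1\t100\t200\tG1\t0\t+", "chr1\t300\t450\tG2\t7\t-")
  writeLines(lines, path)
  iv <- read_bed(path)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, out)
  expect_identical(readLines(out), lines)
  expect_identical(read_bed(out), iv)
})

test_that("bedGraph records cover half-open spans and absent bases read 0", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t10\t13\t2.0", path)
  trk <- read_bedgraph_pair(path, NULL, c(chr1 = 20))
  for (p in 10:12) expect_equal(interval_sum(trk, "chr1", p, p + 1, "+"), 2)
  expect_equal(interval_sum(trk, "chr1", 13, 14, "+"), 0)
  # empty file -> all-zero strand
  empty <- withr::local_tempfile(fileext = ".bedgraph")
  file.create(empty)
  trk0 <- read_bedgraph_pair(empty, NULL, c(chr1 = 20))
  expect_equal(interval_sum(trk0, "chr1", 0, 20, "+"), 0)
  # two abutting records
  writeLines(c("chr1\t0\t5\t1", "chr1\t5\t8\t3"), path)
  trk2 <- read_bedgraph_pair(path, NULL, c(chr1 = 20))
  expect_equal(interval_sum(trk2, "chr1", 0, 8, "+"), 5 * 1 + 3 * 3)
})

test_that("invalid bedGraph input is rejected", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t5\t1", "chr1\t3\t8\t3"), path)
  expect_error(read_bedgraph_pair(path, NULL, c(chr1 = 20)), "overlapping")
  writeLines("chr1\t0\t5\t-1", path)
  expect_error(read_bedgraph_pair(path, NULL, c(chr1 = 20)), "negative")
  writeLines("chrX\t0\t5\t1", path)
  expect_error(read_bedgraph_pair(path, NULL, c(chr1 = 20)),
               "unknown chromosome")
})

test_that("interval_sum equals a naive per-base loop on random sparse tracks", {
  withr::local_seed(101)
  n <- 500
  for (rep in 1:5) {
    plus <- numeric(n); minus <- numeric(n)
    plus[sample.int(n, 40)] <- sample(1:9, 40, replace = TRUE)
    minus[sample.int(n, 40)] <- sample(1:9, 40, replace = TRUE)
    trk <- make_track(plus, minus)
    for (q in 1:20) {
      b <- sort(sample(0:n, 2))
      expect_equal(interval_sum(trk, "chrT", b[1], b[2], "+"),
                   sum(plus[seq_len(n) > b[1] & seq_len(n) <= b[2]]))
      expect_equal(interval_sum(trk, "chrT", b[1], b[2], "-"),
                   sum(minus[seq_len(n) > b[1] & seq_len(n) <= b[2]]))
      expect_equal(interval_sum(trk, "chrT", b[1], b[2], "."),
                   sum((plus + minus)[seq_len(n) > b[1] & seq_len(n) <= b[2]]))
    }
  }
})

test_that("interval_sum is additive over adjacent intervals and 0 when empty", {
  withr::local_seed(7)
  v <- rpois(300, 1)
  trk <- make_track(v)
  expect_equal(interval_sum(trk, "chrT", 42, 42, "+"), 0)
  for (i in 1:10) {
    abc <- sort(sample(0:300, 3))
    expect_equal(interval_sum(trk, "chrT", abc[1], abc[2], "+") +
                   interval_sum(trk, "chrT", abc[2], abc[3], "+"),
                 interval_sum(trk, "chrT", abc[1], abc[3], "+"))
  }
  expect_equal(interval_sum(make_track(rep(2, 1000)), "chrT", 100, 150, "+"),
               100)
  expect_error(interval_sum(trk, "chrZ", 0, 1), "unknown chromosome")
})

test_that("bedGraph round trip reproduces the file", {
  lines <- c("chrT\t3\t10\t2", "chrT\t10\t12\t5", "chrT\t40\t41\t1")
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(lines, path)
  trk <- read_bedgraph_pair(path, NULL, c(chrT = 50))
  out <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph_pair(trk, out)
  expect_identical(readLines(out), lines)
})

test_that("strand_window translates transcript offsets, mirrored on -", {
  gp <- one_gene(4000, 5000, "+")
  w <- strand_window(gp[1, ], 500, 1000, "tes")
  expect_equal(c(w$start, w$end), c(5500, 6000))
  w <- strand_window(gp[1, ], -50, 0, "tes")
  expect_equal(c(w$start, w$end), c(4950, 5000))
  gm <- one_gene(5000, 6000, "-")          # tes at genomic 5000
  w <- strand_window(gm[1, ], 500, 1000, "tes")
  expect_equal(c(w$start, w$end), c(4000, 4500))
  # mirror arithmetic: enumerate transcript-oriented positions one by one
  d_positions <- vapply(500:999, function(d) 5000 - 1 - d, 0)
  expect_equal(sort(d_positions), w$start:(w$end - 1))
  expect_error(strand_window(gp[1, ], 10, 10, "tes"), "offset_start")
})

test_that("strand symmetry: mirrored - gene windows equal + gene windows", {
  n <- 2000
  gp <- one_gene(600, 900, "+")
  gm <- one_gene(n - 900, n - 600, "-")    # coordinate-mirrored copy
  for (off in list(c(0, 100), c(-50, 0), c(20, 60))) {
    wp <- strand_window(gp[1, ], off[1], off[2], "tes")
    wm <- strand_window(gm[1, ], off[1], off[2], "tes")
    expect_equal(wm$start, n - wp$end)
    expect_equal(wm$end, n - wp$start)
  }
})

test_that("gene tables derive TSS/TES by strand and default class to other", {
  g <- gene_table(c("a", "b"), "chr1", c(10, 50), c(30, 80), c("+", "-"),
                  c("histone", "mystery"))
  expect_equal(gene_tss(g), c(10, 80))
  expect_equal(gene_tes(g), c(30, 50))
  expect_equal(g$gene_class, c("histone", "other"))
  expect_error(gene_table("a", "chr1", 30, 30, "+"), "start < end")
})

test_that("read_genes joins the class map and validates strand", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tgA\t0\t+", "chr1\t1000\t1500\tgB\t0\t-"), bed)
  cm <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gA\thistone", cm)
  g <- read_genes(bed, cm)
  expect_equal(g$gene_class, c("histone", "other"))
  writeLines("chr1\t100\t600\tgA\t0\t.", bed)
  expect_error(read_genes(bed), "stranded")
})
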