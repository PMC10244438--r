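test_that("BED parsing maps fields under the half-open convention and sorts", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("track name=test",
               "# a comment",
               "chr2\t50\t80",
               "chr1\t100\t600\tpeak1\t25\t+",
               "chr1\t0\t10"), f)
  pk <- read_intervals(f)
  expect_equal(pk$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(pk$start, c(0, 100, 50))
  expect_equal(pk$end, c(10, 600, 80))
  expect_equal(pk$name[2], "peak1")
  expect_equal(pk$score[2], 25)
  expect_equal(pk$strand[2], "+")
  expect_equal(pk$strand[1], "*")
})

test_that("malformed BED lines are rejected with their line number", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t600\t100"), f)
  expect_error(read_intervals(f), "line 2.*end <= start")
  writeLines(c("chr1\t0\t10", "chr1\tx\t100"), f)
  expect_error(read_intervals(f), "line 2")
  writeLines(c("chr1\t10"), f)
  expect_error(read_intervals(f), "fewer than 3")
})

test_that("an empty BED file is an empty peak set, not an error", {
  f <- tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_equal(nrow(read_intervals(f)), 0)
})

test_that("intervals round-trip through write_intervals/read_intervals", {
  set.seed(7)
  pk <- random_peaks(40)
  pk$name <- sprintf("p%d", seq_len(nrow(pk)))
  pk$score <- seq_len(nrow(pk))
  pk$strand <- sample(c("+", "-", "*"), nrow(pk), replace = TRUE)
  f <- tempfile(fileext = ".bed")
  write_intervals(pk, f)
  back <- read_intervals(f)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$name, pk$name)
  expect_equal(back$strand, pk$strand)
})

test_that("random valid BED text always satisfies the interval invariants", {
  set.seed(11)
  for (trial in 1:20) {
    pk <- random_peaks(sample(1:50, 1))
    f <- tempfile(fileext = ".bed")
    write_intervals(pk, f)
    got <- read_intervals(f)
    expect_true(all(got$end > got$start))
    expect_true(all(got$start >= 0))
    expect_false(is.unsorted(order(got$chrom, got$start, got$end)))
  }
})

test_that("bedGraph binning assigns values across bins with length weighting", {
  f <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t100\t5.0", f)
  tr <- read_signal_track(f, bin_width = 50)
  expect_equal(tr$bins$chr1, c(5, 5))

  writeLines("chr1\t0\t75\t4.0", f)
  tr <- read_signal_track(f, bin_width = 50)
  expect_equal(tr$bins$chr1, c(4, 2))  # second bin half-covered

  # uncovered chromosome reads as zero through region_signal
  expect_warning(v <- region_signal(tr, "chr2", 0, 100), "absent")
  expect_equal(v, 0)
})

test_that("overlapping bedGraph records are rejected", {
  f <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t100\t5", "chr1\t50\t150\t2"), f)
  expect_error(read_signal_track(f, bin_width = 50), "overlapping")
})

test_that("binning conserves integrated signal mass", {
  set.seed(3)
  for (trial in 1:25) {
    rec <- random_records(sample(1:60, 1))
    f <- write_bedgraph(rec)
    w <- sample(c(1, 7, 10, 50), 1)
    tr <- read_signal_track(f, bin_width = w)
    expect_equal(sum(tr$bins$chr1) * w, sum(rec$value * (rec$end - rec$start)),
                 tolerance = 1e-9)
  }
})

test_that("bigWig input matches the bedGraph route", {
  skip_if_not_installed("rtracklayer")
  rec <- data.frame(start = c(0, 100, 400), end = c(100, 250, 430),
                    value = c(2, 5.5, 1))
  fb <- write_bedgraph(rec)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(rec$start + 1, rec$end),
                               score = rec$value,
                               seqlengths = c(chr1 = 1000L))
  fw <- tempfile(fileext = ".bw")
  rtracklayer::export(gr, fw, format = "BigWig")
  t1 <- read_signal_track(fb, bin_width = 10)
  t2 <- read_signal_track(fw, bin_width = 10)
  n <- min(length(t1$bins$chr1), length(t2$bins$chr1))
  expect_equal(t2$bins$chr1[1:n], t1$bins$chr1[1:n])
})

test_that("gene models parse from TSV and GTF-lite with strand-aware TSS", {
  g <- tiny_genes()
  f <- tempfile(fileext = ".tsv")
  write.table(g[, 1:5], f, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- read_gene_model(f)
  expect_equal(gm$tss, c(10000, 50000, 39999))

  fg <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tsrc\tgene\t10001\t15000\t.\t+\t.\tgene_id \"geneA\";",
    "chr1\tsrc\texon\t10001\t11000\t.\t+\t.\tgene_id \"geneA\";",
    "chr2\tsrc\tgene\t30001\t40000\t.\t-\t.\tgene_id \"geneC\";"), fg)
  gm2 <- read_gene_model(fg)
  expect_equal(nrow(gm2), 2)  # exon line skipped
  expect_equal(gm2$start, c(10000, 30000))  # 1-based converted at boundary
  expect_equal(gm2$tss, c(10000, 39999))

  # duplicate ids rejected
  g2 <- rbind(g[, 1:5], g[1, 1:5])
  write.table(g2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_model(f), "duplicate")
})

test_that("DEG tables parse, preserve order, and flag missing columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2fc\tpvalue\tqvalue",
               "ZBTB16\t2.1\t1e-6\t1e-4",
               "ALPL\t-0.5\t0.3\t0.6"), f)
  deg <- read_deg_table(f)
  expect_equal(deg$gene_id, c("ZBTB16", "ALPL"))
  expect_equal(deg$log2fc[1], 2.1)
  expect_equal(deg$pvalue[1], 1e-6)
  expect_equal(deg$qvalue[1], 1e-4)

  writeLines(c("gene\tlog2fc\tpvalue", "A\t1\t0.01", "B\t2\t0.02"), f)
  deg <- read_deg_table(f)
  expect_true(all(is.na(deg$qvalue)))

  writeLines(c("gene\tlog2fc", "A\t1"), f)
  expect_error(read_deg_table(f), "pvalue.*qvalue")

  writeLines(c("gene\tlog2fc\tpvalue", "SP7\t1\t0.01", "SP7\t2\t0.02"), f)
  expect_error(read_deg_table(f), "duplicate.*SP7")
})

test_that("gene lists skip comments and blanks", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# disease genes", "ZBTB16", "", "SP7"), f)
  expect_equal(read_gene_list(f), c("ZBTB16", "SP7"))
})

test_that("signal tracks round-trip through bedGraph writing", {
  set.seed(9)
  rec <- random_records(30)
  tr <- read_signal_track(write_bedgraph(rec), bin_width = 10)
  f2 <- tempfile(fileext = ".bedGraph")
  write_signal_track(tr, f2)
  tr2 <- read_signal_track(f2, bin_width = 10)
  expect_equal(tr2$bins$chr1, tr$bins$chr1[seq_along(tr2$bins$chr1)])
})
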