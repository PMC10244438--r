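test_that("peaks merge across gaps up to and including the stitch distance", {
  pk <- peak_set("chr1", c(0, 5000, 20000), c(1000, 6000, 21000))
  st <- stitch_peaks(pk, stitch_distance = 12500)
  expect_equal(nrow(st), 2)
  expect_equal(st$start, c(0, 20000))
  expect_equal(st$end, c(6000, 21000))
  expect_equal(st$n_constituents, c(2, 1))

  # a gap of exactly the stitch distance merges (inclusive rule)
  pk2 <- peak_set("chr1", c(0, 12600), c(100, 12700))
  expect_equal(nrow(stitch_peaks(pk2, 12500)), 1)
  # one bp more does not
  pk3 <- peak_set("chr1", c(0, 12601), c(100, 12701))
  expect_equal(nrow(stitch_peaks(pk3, 12500)), 2)

  # a single peak stitches to itself
  one <- stitch_peaks(peak_set("chr1", 5, 105), 12500)
  expect_equal(one[, c("start", "end")], data.frame(start = 5, end = 105))

  expect_error(stitch_peaks(pk, -1), ">= 0")
})

test_that("TSS-proximal peaks can be excluded before stitching", {
  genes <- tiny_genes()
  pk <- peak_set("chr1", c(9000, 30000), c(10500, 31000))
  # first peak sits fully inside geneA TSS (10000) +/- 2500
  st <- stitch_peaks(pk, 12500, tss_exclusion = list(genes = genes, window = 2500))
  expect_equal(nrow(st), 1)
  expect_equal(st$start, 30000)
  # without exclusion both survive
  expect_equal(sum(stitch_peaks(pk, 500)$n_constituents), 2)
})

test_that("stitching matches the painted-components oracle on random sets", {
  set.seed(31)
  for (trial in 1:120) {
    pk <- random_peaks(sample(2:120, 1))
    d <- sample(c(0, 10, 200, 5000), 1)
    got <- stitch_peaks(pk, d)
    exp <- oracle_stitch(pk, d)
    expect_equal(got$chrom, exp$chrom)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$n_constituents, exp$n_constituents)
    # partition: every peak in exactly one region
    expect_equal(sum(got$n_constituents), nrow(pk))
    expect_equal(sort(unlist(got$constituents)), seq_len(nrow(pk)))
    # output gaps exceed the stitch distance
    for (ch in unique(got$chrom)) {
      g <- got[got$chrom == ch, ]
      if (nrow(g) > 1)
        expect_true(all(g$start[-1] - g$end[-nrow(g)] > d))
    }
    # idempotence
    again <- stitch_peaks(peak_set(got$chrom, got$start, got$end), d)
    expect_equal(again$start, got$start)
    expect_equal(again$end, got$end)
  }
})

test_that("stitching agrees with GenomicRanges::reduce", {
  skip_if_not_installed("GenomicRanges")
  set.seed(32)
  for (trial in 1:25) {
    pk <- random_peaks(sample(2:200, 1))
    d <- sample(c(0, 100, 2000, 12500), 1)
    got <- stitch_peaks(pk, d)
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1, pk$end)),
      min.gapwidth = d + 1)
    expect_equal(got$start, GenomicRanges::start(gr) - 1)
    expect_equal(got$end, GenomicRanges::end(gr))
  }
})

test_that("scoring ranks regions by integrated signal with deterministic ties", {
  bins <- numeric(200)
  bins[1:20] <- 1; bins[101:120] <- 5
  tr <- signal_track(list(chr1 = bins), bin_width = 50)
  st <- stitch_peaks(peak_set("chr1", c(0, 5000), c(1000, 6000)), 100)
  sc <- score_stitched(st, tr)
  expect_equal(sc$signal, c(1000, 5000))   # ascending
  expect_equal(sc$rank, c(2, 1))           # rank 1 = strongest

  # all-zero track: ties broken by (chrom, start), scoring order-independent
  tz <- const_track(0)
  pk <- peak_set("chr1", c(5000, 1000, 9000), c(5100, 1100, 9100))
  stz <- score_stitched(stitch_peaks(pk, 10), tz)
  expect_equal(stz$signal, rep(0, 3))
  expect_equal(stz$start, c(1000, 5000, 9000))
})

test_that("the slope-1 cutoff reproduces the worked hockey-stick example", {
  s <- c(0, 1, 2, 4, 8, 16, 32, 64)
  orc <- oracle_cutoff(s)
  expect_equal(orc$cutoff_value, 16)      # oracle first
  expect_equal(orc$cutoff_index, 6)       # 1-based (0-based index 5)
  got <- find_se_cutoff(s)
  expect_equal(got$cutoff_value, orc$cutoff_value)
  expect_equal(got$cutoff_index, orc$cutoff_index)
  expect_equal(sum(s > got$cutoff_value), 2)
})

test_that("degenerate curves yield no super-enhancers", {
  # exactly linear: y - x = 0 everywhere, tie-break to the last index
  lin <- find_se_cutoff(c(0, 1, 2, 3, 4))
  expect_equal(lin$cutoff_index, 5)
  expect_equal(lin$cutoff_value, 4)
  expect_equal(sum(c(0, 1, 2, 3, 4) > lin$cutoff_value), 0)
  # flat positive curve
  flat <- find_se_cutoff(c(5, 5, 5, 5))
  expect_equal(flat$cutoff_value, 5)
  expect_equal(flat$cutoff_index, 4)
  # all-zero curve
  zero <- find_se_cutoff(c(0, 0, 0))
  expect_equal(zero$cutoff_value, 0)
  expect_equal(zero$cutoff_index, 3)
  expect_error(find_se_cutoff(3), "at least 2")
  expect_error(find_se_cutoff(c(2, 1, 3)), "ascending")
})

test_that("call_superenhancers composes stitch, score and cutoff", {
  # eight isolated 1 kb peaks whose signals follow the worked example
  amps <- c(0, 1, 2, 4, 8, 16, 32, 64)
  starts <- (0:7) * 1e5
  pk <- peak_set("chr1", starts, starts + 1000)
  bins <- numeric(16000)
  for (i in 1:8) bins[(starts[i] / 50 + 1):(starts[i] / 50 + 20)] <- amps[i]
  tr <- signal_track(list(chr1 = bins), bin_width = 50)
  fit <- call_superenhancers(pk, tr, stitch_distance = 12500)
  expect_s3_class(fit, "se_call")
  expect_equal(nrow(fit$regions), 8)
  expect_equal(fit$cutoff_value, 16 * 1000)
  expect_equal(sum(fit$regions$is_super), 2)
  expect_equal(sum(!fit$regions$is_super), 6)

  # positive scaling leaves the SE/TE membership unchanged
  tr10 <- signal_track(lapply(tr$bins, `*`, 10), bin_width = 50)
  fit10 <- call_superenhancers(pk, tr10, stitch_distance = 12500)
  expect_equal(fit10$regions$is_super, fit$regions$is_super)

  # equal signals on isolated peaks: flat curve, zero SEs
  fit_flat <- call_superenhancers(pk, const_track(2, n_bins = 16000),
                                  stitch_distance = 100)
  expect_equal(sum(fit_flat$regions$is_super), 0)
})

test_that("the SE set is always a top-k suffix obeying the cutoff rule", {
  set.seed(33)
  for (trial in 1:50) {
    n <- sample(2:80, 1)
    s <- sort(round(runif(n, 0, 1000)))
    cut <- find_se_cutoff(s)
    is_super <- s > cut$cutoff_value
    # membership is equivalent to the strict cutoff comparison
    expect_equal(is_super, s > cut$cutoff_value)
    # suffix property: once super, all later (larger) entries are super
    if (any(is_super)) expect_true(all(is_super[which(is_super)[1]:n]))
  }
})

test_that("constituent enhancers are the >=1 bp overlapping peaks in order", {
  pk <- peak_set("chr1", c(500, 2000, 4000, 6000, 8000, 9990, 20000),
                 c(900, 2500, 4500, 6500, 8500, 10050, 21000))
  se <- data.frame(chrom = "chr1", start = 0, end = 10000)
  cons <- constituent_enhancers(se, pk)
  expect_equal(nrow(cons), 6)              # straddling peak included
  expect_equal(cons$start, c(500, 2000, 4000, 6000, 8000, 9990))
  none <- constituent_enhancers(data.frame(chrom = "chr2", start = 0,
                                           end = 1e6), pk)
  expect_equal(nrow(none), 0)
})

test_that("SE call artifacts round-trip to disk", {
  pk <- peak_set("chr1", c(0, 5e4, 1e5), c(1000, 5.1e4, 1.01e5))
  bins <- numeric(4000); bins[1:20] <- 50; bins[1001:1020] <- 2
  bins[2001:2020] <- 1
  fit <- call_superenhancers(pk, signal_track(list(chr1 = bins), bin_width = 50))
  pre <- file.path(tempdir(), "toy")
  files <- write_se_call(fit, pre)
  tab <- read.table(paste0(pre, "_stitched.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$is_super), sum(fit$regions$is_super))
  expect_equal(nrow(read_intervals(paste0(pre, "_SE.bed"))),
               sum(fit$regions$is_super))
  expect_equal(nrow(read_intervals(paste0(pre, "_TE.bed"))),
               sum(!fit$regions$is_super))
})
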