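test_that("gain/lost/shared classification follows presence/absence overlap", {
  ctrl <- data.frame(chrom = "chr1", start = 0, end = 10000)
  trt <- data.frame(chrom = "chr1", start = c(500, 50000), end = c(9000, 60000))
  dyn <- classify_dynamics(ctrl, trt)
  expect_equal(dyn$gain$start, 50000)
  expect_equal(nrow(dyn$lost), 0)
  expect_equal(dyn$shared$start, 500)
  expect_equal(dyn$shared_control$start, 0)

  # swapping the conditions swaps gain and lost exactly
  swp <- classify_dynamics(trt, ctrl)
  expect_equal(nrow(swp$gain), 0)
  expect_equal(swp$lost$start, 50000)
  expect_equal(nrow(swp$shared), 1)

  # empty control: everything treated is gain
  dyn0 <- classify_dynamics(ctrl[0, ], trt)
  expect_equal(nrow(dyn0$gain), 2)
  expect_equal(nrow(dyn0$lost), 0)
})

test_that("the overlap fraction rule gates shared status by the shorter region", {
  ctrl <- data.frame(chrom = "chr1", start = 0, end = 1000)
  trt <- data.frame(chrom = "chr1", start = 900, end = 2900)  # 100 bp overlap
  # shorter region is 1000 bp; 100 bp = 10%
  expect_equal(nrow(classify_dynamics(ctrl, trt, min_overlap_frac = 0.05)$shared), 1)
  expect_equal(nrow(classify_dynamics(ctrl, trt, min_overlap_frac = 0.2)$shared), 0)
  expect_error(classify_dynamics(ctrl, trt, min_overlap_frac = 1.5), "\\[0, 1\\]")
})

test_that("classification partitions both input sets and matches the all-pairs oracle", {
  set.seed(41)
  for (trial in 1:40) {
    ctrl <- random_peaks(sample(1:60, 1), span = 5e4)
    trt <- random_peaks(sample(1:60, 1), span = 5e4)
    f <- sample(c(0, 0.25, 0.5), 1)
    dyn <- classify_dynamics(ctrl, trt, min_overlap_frac = f)
    orc <- oracle_classify(ctrl, trt, f)
    expect_equal(nrow(dyn$gain), nrow(orc$gain))
    expect_equal(dyn$gain$start, orc$gain$start)
    expect_equal(dyn$lost$start, orc$lost$start)
    expect_equal(sort(dyn$shared$start), sort(orc$shared$start))
    # every treated SE is gain or shared exactly once
    expect_equal(nrow(dyn$gain) + nrow(dyn$shared), nrow(trt))
  }
})

test_that("consensus requires a representative in every dataset", {
  common <- data.frame(chrom = "chr1", start = 100000, end = 150000)
  sets <- lapply(1:5, function(d) {
    jitter <- d * 1000
    sort_intervals(rbind(
      data.frame(chrom = "chr1", start = 100000 + jitter,
                 end = 150000 - jitter),
      data.frame(chrom = "chr2", start = d * 1e6, end = d * 1e6 + 5000)))
  })
  names(sets) <- paste0("ds", 1:5)
  cons <- consensus_regions(sets)
  expect_equal(nrow(cons$common_regions), 1)
  expect_equal(cons$common_regions$chrom, "chr1")
  # the reported interval is the intersection span of the representatives
  expect_equal(cons$common_regions$start, 105000)
  expect_equal(cons$common_regions$end, 145000)

  # one dataset lacking the locus empties the consensus
  sets2 <- sets
  sets2$ds3 <- sets2$ds3[sets2$ds3$chrom != "chr1", ]
  expect_equal(nrow(consensus_regions(sets2)$common_regions), 0)

  # dataset order does not matter
  perm <- consensus_regions(sets[c(4, 2, 5, 1, 3)])
  expect_equal(perm$common_regions[, c("chrom", "start", "end")],
               cons$common_regions[, c("chrom", "start", "end")])

  expect_error(consensus_regions(sets[1]), "at least 2")
})

test_that("consensus shrinks monotonically as datasets are added", {
  set.seed(42)
  base <- data.frame(chrom = "chr1", start = (0:19) * 1e5,
                     end = (0:19) * 1e5 + 2e4)
  sets <- lapply(1:4, function(d) {
    keep <- sort(sample(20, 14))
    sort_intervals(data.frame(chrom = "chr1", start = base$start[keep] + d * 100,
                              end = base$end[keep] - d * 100))
  })
  names(sets) <- paste0("d", 1:4)
  n_all <- nrow(consensus_regions(sets)$common_regions)
  n_sub <- nrow(consensus_regions(sets[1:2])$common_regions)
  expect_lte(n_all, n_sub)
  expect_lte(n_all, min(vapply(sets, nrow, 0L)))
})

test_that("nearest-TSS annotation is strand-aware with deterministic ties", {
  genes <- tiny_genes()
  # center 20000: geneA TSS 10000 (d = 10000) beats geneB TSS 50000
  ann <- annotate_nearest_tss(data.frame(chrom = "chr1", start = 19000,
                                         end = 21000), genes)
  expect_equal(ann$gene_id, "geneA")
  expect_equal(ann$distance, 10000)

  # minus-strand gene: TSS at end - 1 = 39999
  ann2 <- annotate_nearest_tss(data.frame(chrom = "chr2", start = 44000,
                                          end = 46000), genes)
  expect_equal(ann2$gene_id, "geneC")
  expect_equal(ann2$distance, 45000 - 39999)

  # center inside the gene body reports distance 0
  ann3 <- annotate_nearest_tss(data.frame(chrom = "chr1", start = 11000,
                                          end = 13000), genes)
  expect_equal(ann3$distance, 0)

  # equidistant TSSs resolve to the smaller coordinate
  g2 <- data.frame(gene_id = c("gLeft", "gRight"), chrom = "chr1",
                   start = c(0, 30000), end = c(100, 30100),
                   strand = "+", tss = c(15000 - 5000, 15000 + 5000))
  ann4 <- annotate_nearest_tss(data.frame(chrom = "chr1", start = 14000,
                                          end = 16001), genes = g2)
  expect_equal(ann4$gene_id, "gLeft")

  expect_error(annotate_nearest_tss(data.frame(chrom = "chr1", start = 0,
                                               end = 10), genes[0, ]),
               "empty gene model")
  expect_warning(
    annX <- annotate_nearest_tss(data.frame(chrom = "chrX", start = 0,
                                            end = 10), genes),
    "absent")
  expect_true(is.na(annX$gene_id))
})
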