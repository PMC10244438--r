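# Small in-code fixtures shared across tests.

# constant-value track on one chromosome
const_track <- function(value, n_bins = 1000, w = 50, chrom = "chr1") {
  signal_track(stats::setNames(list(rep(value, n_bins)), chrom), bin_width = w)
}

# random sorted peaks (overlaps allowed) on 1-2 chromosomes
random_peaks <- function(n, span = 2e5, chroms = c("chr1", "chr2")) {
  chrom <- sample(chroms, n, replace = TRUE)
  parts <- lapply(unique(chrom), function(ch) {
    k <- sum(chrom == ch)
    starts <- sort(sample.int(span, k))
    widths <- sample(10:500, k, replace = TRUE)
    data.frame(chrom = ch, start = starts, end = starts + widths)
  })
  sort_intervals(do.call(rbind, parts))
}

# random non-overlapping bedGraph records on one chromosome
random_records <- function(n, span = 1e4) {
  edges <- sort(sample.int(span, 2 * n))
  data.frame(start = edges[seq(1, 2 * n, 2)], end = edges[seq(2, 2 * n, 2)],
             value = round(stats::runif(n, 0, 10), 3))
}

write_bedgraph <- function(rec, chrom = "chr1", path = tempfile(fileext = ".bedGraph")) {
  writeLines(paste(chrom, rec$start, rec$end, rec$value, sep = "\t"), path)
  path
}

# a tiny gene model table
tiny_genes <- function() {
  data.frame(gene_id = c("geneA", "geneB", "geneC"),
             chrom = c("chr1", "chr1", "chr2"),
             start = c(10000, 50000, 30000),
             end = c(15000, 55000, 40000),
             strand = c("+", "+", "-"),
             tss = c(10000, 50000, 39999))
}
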