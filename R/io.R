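#' Read enhancer peaks from a BED file
#'
#' Reads BED3/BED6 under the half-open convention, skipping `track`,
#' `browser` and `#` comment lines. Chromosome names are taken verbatim
#' unless `harmonize_chr = TRUE`, which prepends `"chr"` to names lacking it.
#'
#' @param path BED file.
#' @param source,marker dataset and marker labels stored on the result.
#' @param harmonize_chr logical; add a `chr` prefix where missing.
#' @return A [peak_set] sorted by (chrom, start, end). An empty file yields
#'   an empty peak set.
#' @export
read_intervals <- function(path, source = basename(path), marker = NA_character_,
                           harmonize_chr = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(peak_set(character(), numeric(), numeric(),
                    source = source, marker = marker))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 fields", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": non-integer or negative coordinate", call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": end <= start", call. = FALSE)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   "*")
  strand[!strand %in% c("+", "-")] <- "*"
  if (harmonize_chr) chrom <- ifelse(grepl("^chr", chrom), chrom,
                                     paste0("chr", chrom))
  peak_set(chrom, start, end, name = name, score = score, strand = strand,
           source = source, marker = marker)
}

#' Read a coverage track into fixed-width bins
#'
#' Reads a 4-column bedGraph (or a bigWig via the rtracklayer package) into
#' per-chromosome fixed-width bins. A record spanning several bins assigns
#' its value to each; a record partially covering a bin contributes its
#' length-weighted average, so integrated signal mass is conserved.
#' Uncovered positions are zero.
#'
#' @param path bedGraph or bigWig file.
#' @param bin_width bin width in bp (>= 1).
#' @param format `"bedGraph"`, `"bigWig"` or `"auto"` (by extension).
#' @param library_size optional total mapped reads, required later for RPKM.
#' @return A [signal_track].
#' @export
read_signal_track <- function(path, bin_width = 50, format = c("auto", "bedGraph", "bigWig"),
                              library_size = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigWig" else "bedGraph"
  }
  if (format == "bigWig") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("bigWig input requires the rtracklayer package", call. = FALSE)
    gr <- as.data.frame(rtracklayer::import(path, format = "BigWig"))
    rec <- data.frame(chrom = as.character(gr$seqnames),
                      start = gr$start - 1,  # 1-based -> 0-based half-open
                      end = gr$end,
                      value = gr$score)
  } else {
    rec <- data.table::fread(path, header = FALSE, sep = "\t",
                             col.names = c("chrom", "start", "end", "value"),
                             colClasses = list(character = 1, numeric = 2:4),
                             skip = 0, blank.lines.skip = TRUE,
                             data.table = FALSE)
    cm <- grepl("^(track|browser|#)", rec$chrom)
    if (any(cm)) rec <- rec[!cm, , drop = FALSE]
    rec$start <- as.numeric(rec$start)
    rec$end <- as.numeric(rec$end)
    rec$value <- as.numeric(rec$value)
    if (any(is.na(rec$start) | is.na(rec$end) | is.na(rec$value)))
      stop("bedGraph parse error: non-numeric field", call. = FALSE)
  }
  if (nrow(rec) && any(rec$end <= rec$start))
    stop("bedGraph record with end <= start", call. = FALSE)
  bins <- list()
  for (chr in unique(rec$chrom)) {
    r <- rec[rec$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("overlapping bedGraph records on ", chr, call. = FALSE)
    n_bins <- ceiling(max(r$end) / bin_width)
    bins[[chr]] <- bin_records(r$start, r$end, r$value, bin_width, n_bins)
  }
  signal_track(bins, bin_width = bin_width, library_size = library_size)
}

# Length-weighted binning of non-overlapping, sorted step records.
# Bin b (0-based) value = integral of the step function over
# [b*w, (b+1)*w) divided by w. Fully vectorized via the cumulative
# integral evaluated at bin edges.
bin_records <- function(starts, ends, values, w, n_bins) {
  if (!length(starts)) return(numeric(n_bins))
  areas <- values * (ends - starts)
  cumarea <- c(0, cumsum(areas))
  # A(p): integral of step function over [0, p)
  A <- function(p) {
    j <- findInterval(p, starts)        # record index at or before p
    base <- cumarea[pmax(j, 0) + 1]
    inside <- j >= 1 & p < ends[pmax(j, 1)]
    adj <- numeric(length(p))
    ji <- j[inside]
    adj[inside] <- values[ji] * (p[inside] - starts[ji]) - areas[ji]
    base + adj
  }
  edges <- (0:n_bins) * w
  v <- diff(A(edges)) / w
  # the cumulative form can leave -eps residue on zero bins
  eps <- 1e-9 * max(abs(v), 1)
  v[v < 0 & v >= -eps] <- 0
  v
}

#' Read a gene model
#'
#' Accepts either a TSV with header columns `gene_id`, `chrom`, `start`,
#' `end`, `strand` (0-based half-open) or a GTF-lite file (only lines with
#' feature type `gene` are used; 1-based inclusive coordinates are converted
#' at the boundary). The strand-aware transcription start site is computed
#' as `start` on the + strand and `end - 1` on the - strand.
#'
#' @param path gene model file.
#' @param format `"tsv"`, `"gtf"` or `"auto"`.
#' @return data frame with columns gene_id, chrom, start, end, strand, tss.
#' @export
read_gene_model <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  if (format == "gtf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", logical(1))
    fields <- fields[keep]
    if (!length(fields)) stop("no gene lines in GTF: ", path, call. = FALSE)
    gid <- vapply(fields, function(f) {
      m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
      if (length(m) < 2) NA_character_ else m[2]
    }, "")
    genes <- data.frame(
      gene_id = gid,
      chrom = vapply(fields, `[[`, "", 1L),
      start = as.numeric(vapply(fields, `[[`, "", 4L)) - 1,  # 1-based -> 0-based
      end = as.numeric(vapply(fields, `[[`, "", 5L)),
      strand = vapply(fields, `[[`, "", 7L)
    )
  } else {
    genes <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(genes))
    if (length(miss))
      stop("gene model missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene model: ",
         genes$gene_id[duplicated(genes$gene_id)][1], call. = FALSE)
  validate_intervals(genes, "gene model")
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  genes
}

#' Read a differential-expression table
#'
#' TSV with a header; column names for the gene identifier, log2 fold
#' change, p-value and q-value are configurable. At least one of the p/q
#' columns must be present. Missing q-values are left missing for
#' [bh_adjust] to fill; rows keep their input order.
#'
#' @param path TSV file.
#' @param gene_col,lfc_col,p_col,q_col column names to look for.
#' @return data frame with columns gene_id, log2fc, pvalue, qvalue.
#' @export
read_deg_table <- function(path, gene_col = "gene", lfc_col = "log2fc",
                           p_col = "pvalue", q_col = "qvalue") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(col) if (col %in% names(tab)) tab[[col]] else NULL
  gene <- pick(gene_col); lfc <- pick(lfc_col)
  if (is.null(gene) || is.null(lfc))
    stop("DEG table needs columns '", gene_col, "' and '", lfc_col, "'",
         call. = FALSE)
  p <- pick(p_col); q <- pick(q_col)
  if (is.null(p) && is.null(q))
    stop("DEG table needs a '", p_col, "' and/or '", q_col, "' column",
         call. = FALSE)
  if (anyDuplicated(gene))
    stop("duplicate gene_id in DEG table: ", gene[duplicated(gene)][1],
         call. = FALSE)
  if (any(!is.finite(lfc)))
    stop("non-finite log2fc in DEG table", call. = FALSE)
  out <- data.frame(gene_id = as.character(gene), log2fc = as.numeric(lfc),
                    pvalue = if (is.null(p)) NA_real_ else as.numeric(p),
                    qvalue = if (is.null(q)) NA_real_ else as.numeric(q),
                    stringsAsFactors = FALSE)
  chk <- function(v, nm) {
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(nm, " outside [0, 1] in DEG table", call. = FALSE)
  }
  chk(out$pvalue, p_col); chk(out$qvalue, q_col)
  if (any(is.na(out$pvalue) & is.na(out$qvalue)))
    stop("DEG row with neither p-value nor q-value", call. = FALSE)
  out
}

#' Read a plain gene list
#'
#' One gene per line; `#` comments and blank lines skipped.
#' @param path text file.
#' @return character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Write a signal track as bedGraph
#'
#' Adjacent equal-valued bins are merged into one record; zero-valued runs
#' are omitted (uncovered convention).
#' @param track a [signal_track].
#' @param path output bedGraph.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  w <- track$bin_width
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (chr in names(track$bins)) {
    v <- track$bins[[chr]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * w
    starts <- ends - r$lengths * w
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(chr,
                     format(starts[keep], scientific = FALSE, trim = TRUE),
                     format(ends[keep], scientific = FALSE, trim = TRUE),
                     format(r$values[keep], scientific = FALSE, trim = TRUE),
                     sep = "\t"),
               con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}
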