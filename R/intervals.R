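#' Genomic interval tables
#'
#' All coordinates in this package are 0-based, half-open (BED native):
#' `start` is the first base of the region, `end` is one past the last.
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `name`, `score`, `strand`; a peak set additionally carries
#' `source` and `marker` attributes identifying the dataset it came from.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `end > start`.
#' @param name optional labels.
#' @param score optional numeric scores.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param source dataset label.
#' @param marker enhancer marker label (e.g. `"H3K27ac"`, `"BRD4"`).
#' @return A `peak_set` data frame sorted by (chrom, start, end).
#' @examples
#' peak_set(c("chr1", "chr1"), c(0, 5000), c(1000, 6000))
#' @export
peak_set <- function(chrom, start, end, name = NA_character_,
                     score = 0, strand = "*",
                     source = NA_character_, marker = NA_character_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df <- sort_intervals(df)
  attr(df, "source") <- source
  attr(df, "marker") <- marker
  class(df) <- c("peak_set", "data.frame")
  df
}

validate_intervals <- function(df, where = "interval set") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(where, ": empty chromosome name", call. = FALSE)
  if (any(df$start < 0))
    stop(where, ": negative start coordinate", call. = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(where, ": end <= start at row ", bad[1], call. = FALSE)
  if (!is.null(df$strand) && any(!df$strand %in% c("+", "-", "*", ".")))
    stop(where, ": strand must be one of +, -, *", call. = FALSE)
  invisible(df)
}

sort_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Width of intervals
#' @param df an interval data frame.
#' @return numeric widths in bp.
#' @keywords internal
interval_width <- function(df) df$end - df$start

# Overlap in bp between one interval (chrom/start/end scalars) and each row
# of a sorted interval table restricted to the same chromosome.
overlap_bp <- function(chrom, start, end, df) {
  same <- df$chrom == chrom
  ov <- numeric(nrow(df))
  if (any(same)) {
    ov[same] <- pmax(0, pmin(end, df$end[same]) - pmax(start, df$start[same]))
  }
  ov
}

#' Write intervals as BED
#'
#' Writes BED6 (chrom, start, end, name, score, strand), tab-separated,
#' UTF-8, LF line endings. Missing names are written as `.`.
#'
#' @param df interval data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    name = if (is.null(df$name)) "." else ifelse(is.na(df$name), ".", df$name),
    score = if (is.null(df$score)) 0 else ifelse(is.na(df$score), 0, df$score),
    strand = if (is.null(df$strand)) "*" else ifelse(is.na(df$strand), "*", df$strand)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(out))
    writeLines(do.call(paste, c(out, sep = "\t")), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
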