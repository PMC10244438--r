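#' Binned coverage track
#'
#' A signal track holds per-chromosome vectors of fixed-width bins starting
#' at position 0, the bin width, the library size (total mapped reads, if
#' known) and whether values are raw or RPKM-normalized.
#'
#' @param bins named list of non-negative numeric vectors, one per chromosome.
#' @param bin_width bin width in bp (>= 1).
#' @param library_size total mapped reads, or `NA` if unknown.
#' @param normalized `"raw"` or `"RPKM"`.
#' @return A `signal_track` object.
#' @export
signal_track <- function(bins, bin_width, library_size = NA_real_,
                         normalized = c("raw", "RPKM")) {
  normalized <- match.arg(normalized)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  if (!is.list(bins) || (length(bins) && is.null(names(bins))))
    stop("bins must be a named list of numeric vectors", call. = FALSE)
  if (normalized == "raw" && any(vapply(bins, function(v) any(v < 0), logical(1))))
    stop("raw track has negative bin values", call. = FALSE)
  structure(list(bins = bins, bin_width = bin_width,
                 library_size = library_size, normalized = normalized),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  nb <- sum(vapply(x$bins, length, 0L))
  cat("signal_track:", length(x$bins), "chromosome(s),", nb, "bins of",
      x$bin_width, "bp (", x$normalized, ")\n")
  invisible(x)
}

#' RPKM-normalize a coverage track
#'
#' Converts per-bin read counts to reads per kilobase per million mapped
#' reads: each bin value c becomes `c * 1e9 / (bin_width * library_size)`.
#'
#' @param track a raw [signal_track].
#' @param library_size total mapped reads; defaults to the track's own.
#' @return An RPKM-normalized [signal_track].
#' @export
rpkm_normalize <- function(track, library_size = track$library_size) {
  if (track$normalized != "raw")
    stop("track is already normalized; refusing to normalize twice",
         call. = FALSE)
  if (is.na(library_size) || library_size <= 0)
    stop("library_size must be a positive read count", call. = FALSE)
  # computed as c * 1e9 / (w * N) per bin so integer inputs hit the
  # closed form exactly
  denom <- track$bin_width * library_size
  track$bins <- lapply(track$bins, function(v) v * 1e9 / denom)
  track$library_size <- library_size
  track$normalized <- "RPKM"
  track
}

# Integral of track over [start, end) on one chromosome, in value x bp.
# Absent chromosomes and out-of-bounds positions read as zero.
track_area <- function(track, chrom, start, end, warn_absent = TRUE) {
  bins <- track$bins[[chrom]]
  if (is.null(bins)) {
    if (warn_absent)
      warning("chromosome ", chrom, " absent from track; treated as zero",
              call. = FALSE)
    return(0)
  }
  w <- track$bin_width
  len <- length(bins) * w
  s <- max(start, 0); e <- min(end, len)
  if (e <= s) return(0)
  b0 <- floor(s / w); b1 <- floor((e - 1) / w)
  idx <- b0:b1
  ov <- pmin(e, (idx + 1) * w) - pmax(s, idx * w)
  sum(bins[idx + 1] * ov)
}

#' Integrated signal over a region
#'
#' Returns the integral (bin value times overlapped width, in value x bp)
#' of the track over the region, optionally minus the same quantity for a
#' control track, clamped at zero. This is the score by which stitched
#' enhancers are ranked.
#'
#' @param track a [signal_track].
#' @param chrom,start,end the region (0-based half-open). Alternatively
#'   `chrom` may be a single-row interval data frame.
#' @param control optional control/input [signal_track] with the same
#'   bin width.
#' @return non-negative numeric signal area.
#' @export
region_signal <- function(track, chrom, start = NULL, end = NULL,
                          control = NULL) {
  if (is.data.frame(chrom)) {
    start <- chrom$start[1]; end <- chrom$end[1]; chrom <- chrom$chrom[1]
  }
  a <- track_area(track, chrom, start, end)
  if (!is.null(control)) {
    if (control$bin_width != track$bin_width)
      stop("control track bin_width differs from signal track", call. = FALSE)
    a <- max(0, a - track_area(control, chrom, start, end, warn_absent = FALSE))
  }
  a
}

# Mean track value over [start, end): area / width, zero-width -> 0.
track_mean <- function(track, chrom, start, end) {
  if (end <= start) return(0)
  track_area(track, chrom, start, end, warn_absent = FALSE) / (end - start)
}

#' Signal profile matrix over regions
#'
#' Builds a computeMatrix-style positional matrix: one row per region.
#' In `reference-point` mode each row samples `[center - flank,
#' center + flank)` into `n_bins` equal bins, with the region center at
#' `floor((start + end) / 2)`. In `scale-regions` mode the region body is
#' rescaled to `n_bins` bins, flanked on each side by `n_flank_bins` bins
#' covering `flank` bp. Rows for minus-strand regions are reversed;
#' positions beyond chromosome bounds contribute zero.
#'
#' @param track a [signal_track].
#' @param regions interval data frame (a [peak_set] or any chrom/start/end
#'   table, optionally with strand).
#' @param mode `"reference-point"` or `"scale-regions"`.
#' @param flank bp of flank on each side (>= 0).
#' @param n_bins number of bins for the window (reference-point) or region
#'   body (scale-regions).
#' @param n_flank_bins bins per flank in scale-regions mode.
#' @return A `profile_matrix`: numeric matrix with attributes `mode`,
#'   `flank`, `n_body_bins` and column names giving bin offsets.
#' @export
profile_matrix <- function(track, regions,
                           mode = c("reference-point", "scale-regions"),
                           flank = 5000, n_bins = 50,
                           n_flank_bins = ceiling(n_bins / 2)) {
  mode <- match.arg(mode)
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  n <- nrow(regions)
  ncol_out <- if (mode == "reference-point") n_bins else n_bins + 2 * n_flank_bins
  m <- matrix(0, nrow = n, ncol = ncol_out)
  strand <- if (is.null(regions$strand)) rep("*", n) else regions$strand
  sample_window <- function(chrom, a, b, k) {
    # k equal bins over [a, b); mean value per bin
    if (k < 1) return(numeric(0))
    edges <- a + (b - a) * (0:k) / k
    vapply(seq_len(k), function(i)
      track_mean(track, chrom, edges[i], edges[i + 1]), 0)
  }
  for (i in seq_len(n)) {
    chrom <- regions$chrom[i]
    if (mode == "reference-point") {
      center <- floor((regions$start[i] + regions$end[i]) / 2)
      row <- sample_window(chrom, center - flank, center + flank, n_bins)
    } else {
      row <- c(
        if (n_flank_bins > 0 && flank > 0)
          sample_window(chrom, regions$start[i] - flank, regions$start[i],
                        n_flank_bins)
        else rep(0, n_flank_bins),
        sample_window(chrom, regions$start[i], regions$end[i], n_bins),
        if (n_flank_bins > 0 && flank > 0)
          sample_window(chrom, regions$end[i], regions$end[i] + flank,
                        n_flank_bins)
        else rep(0, n_flank_bins))
    }
    if (strand[i] == "-") row <- rev(row)
    m[i, ] <- row
  }
  if (mode == "reference-point") {
    offs <- -flank + (2 * flank) * (seq_len(n_bins) - 0.5) / n_bins
    colnames(m) <- sprintf("%.0f", offs)
  } else {
    colnames(m) <- c(sprintf("u%d", seq_len(n_flank_bins)),
                     sprintf("b%d", seq_len(n_bins)),
                     sprintf("d%d", seq_len(n_flank_bins)))
  }
  structure(m, mode = mode, flank = flank,
            n_body_bins = if (mode == "scale-regions") n_bins else NULL,
            class = c("profile_matrix", "matrix", "array"))
}

#' Export a profile matrix as TSV
#'
#' Header row carries the bin offsets/labels.
#' @param pm a [profile_matrix].
#' @param path output TSV (a `.gz` suffix gzip-compresses).
#' @return `path`, invisibly.
#' @export
export_profile_matrix <- function(pm, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(pm), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(pm))
    writeLines(apply(pm, 1, function(r) paste(format(r, trim = TRUE),
                                              collapse = "\t")),
               con, useBytes = TRUE)
  invisible(path)
}

#' Render a profile heatmap
#'
#' Convenience wrapper drawing the matrix with rows ordered by descending
#' row mean, as profile heatmaps conventionally are.
#' @param pm a [profile_matrix].
#' @param main plot title.
#' @param col color ramp.
#' @return the row order used, invisibly.
#' @export
plot_profile_heatmap <- function(pm, main = "signal profile",
                                 col = grDevices::hcl.colors(64, "YlOrRd",
                                                             rev = TRUE)) {
  ord <- order(rowMeans(pm), decreasing = TRUE)
  graphics::image(t(pm[rev(ord), , drop = FALSE]), col = col, axes = FALSE,
                  main = main, useRaster = TRUE)
  invisible(ord)
}
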