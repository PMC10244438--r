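#' Stitch enhancer peaks
#'
#' Merges consecutive peaks on a chromosome into one stitched region
#' whenever the gap between them (next start minus current region end) is
#' at most `stitch_distance`; overlapping peaks always merge. Every peak
#' belongs to exactly one stitched region. Optionally, peaks falling fully
#' inside a window around any annotated TSS are removed before stitching
#' (promoter-proximal exclusion, off by default).
#'
#' @param peaks a [peak_set] or interval data frame, sorted.
#' @param stitch_distance maximum gap in bp to merge across (default
#'   12500, i.e. 12.5 kb).
#' @param tss_exclusion `NULL`, or `list(genes = <gene model>, window = bp)`;
#'   peaks fully inside `TSS +/- window` are dropped before stitching.
#' @return data frame of stitched regions: chrom, start, end,
#'   n_constituents, plus a list column `constituents` of row indices into
#'   the (filtered, sorted) input peaks, stored as attribute
#'   `"peaks_used"`.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss_exclusion = NULL) {
  if (stitch_distance < 0) stop("stitch_distance must be >= 0", call. = FALSE)
  peaks <- sort_intervals(as.data.frame(peaks))
  if (!is.null(tss_exclusion)) {
    genes <- tss_exclusion$genes
    win <- if (is.null(tss_exclusion$window)) 2500 else tss_exclusion$window
    if (nrow(peaks)) {
      drop <- vapply(seq_len(nrow(peaks)), function(i) {
        g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
        any(peaks$start[i] >= g$tss - win & peaks$end[i] <= g$tss + win + 1)
      }, logical(1))
      peaks <- peaks[!drop, , drop = FALSE]
    }
  }
  n <- nrow(peaks)
  out <- list()
  if (n) {
    # group id increments where the gap to the running region end exceeds
    # the stitch distance
    grp <- integer(n)
    gid <- 0L
    cur_end <- -Inf
    cur_chrom <- ""
    for (i in seq_len(n)) {
      if (peaks$chrom[i] != cur_chrom ||
          peaks$start[i] - cur_end > stitch_distance) {
        gid <- gid + 1L
        cur_chrom <- peaks$chrom[i]
        cur_end <- peaks$end[i]
      } else {
        cur_end <- max(cur_end, peaks$end[i])
      }
      grp[i] <- gid
    }
    idx <- split(seq_len(n), grp)
    out <- data.frame(
      chrom = vapply(idx, function(j) peaks$chrom[j[1]], ""),
      start = vapply(idx, function(j) min(peaks$start[j]), 0),
      end = vapply(idx, function(j) max(peaks$end[j]), 0),
      n_constituents = lengths(idx)
    )
    out$constituents <- unname(idx)
  } else {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_constituents = integer())
    out$constituents <- list()
  }
  rownames(out) <- NULL
  attr(out, "peaks_used") <- peaks
  attr(out, "stitch_distance") <- stitch_distance
  out
}

#' Score stitched regions by integrated signal
#'
#' Each region's signal is [region_signal] over its interval (optionally
#' control-subtracted and clamped at zero). Regions are returned sorted
#' ascending by signal, ties broken by (chrom, start); ranks are assigned
#' descending so rank 1 is the strongest region.
#'
#' @param regions stitched regions from [stitch_peaks].
#' @param track a [signal_track].
#' @param control optional control [signal_track].
#' @return the regions with `signal` and `rank` columns, ascending by signal.
#' @export
score_stitched <- function(regions, track, control = NULL) {
  n <- nrow(regions)
  sig <- vapply(seq_len(n), function(i)
    region_signal(track, regions$chrom[i], regions$start[i], regions$end[i],
                  control = control), 0)
  regions$signal <- pmax(sig, 0)
  ord <- order(regions$signal, regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  regions$rank <- rev(seq_len(n))
  rownames(regions) <- NULL
  regions
}

#' Rank-signal slope-1 cutoff
#'
#' Finds the tangent point of the unit-slope line on the scaled
#' rank-signal ("hockey-stick") curve. With signals sorted ascending and
#' scaled to the unit square (`x_i = i/(n-1)`, `y_i = s_i/max(s)`,
#' `i = 0..n-1`), the cutoff sits at `argmin_i (y_i - x_i)`; regions whose
#' signal exceeds the cutoff value are super-enhancers. Ties in the argmin
#' resolve to the largest index, so flat or exactly linear curves yield no
#' super-enhancers.
#'
#' @param signals ascending non-negative numeric vector, length >= 2.
#'   Negative values (possible after control subtraction) are clamped to 0.
#' @return list with `cutoff_value`, `cutoff_index` (1-based position in
#'   the ascending order), and the scaled curve `scaled_x`, `scaled_y`.
#' @export
find_se_cutoff <- function(signals) {
  n <- length(signals)
  if (n < 2) stop("need at least 2 signals to place a cutoff", call. = FALSE)
  signals <- pmax(as.numeric(signals), 0)
  if (is.unsorted(signals)) stop("signals must be sorted ascending", call. = FALSE)
  x <- (seq_len(n) - 1) / (n - 1)
  smax <- signals[n]
  if (smax == 0) {
    # degenerate all-zero curve: no super-enhancers
    return(list(cutoff_value = 0, cutoff_index = n, scaled_x = x,
                scaled_y = rep(0, n)))
  }
  y <- signals / smax
  d <- y - x
  i <- max(which(d == min(d)))
  list(cutoff_value = signals[i], cutoff_index = i, scaled_x = x, scaled_y = y)
}

#' Call super-enhancers from peaks and coverage
#'
#' The full ROSE-style procedure: enhancer peaks are stitched within
#' `stitch_distance`, stitched regions are scored by integrated coverage
#' signal and ranked, and the SE/TE partition is set at the slope-1 tangent
#' point of the scaled rank-signal curve. A region is a super-enhancer iff
#' its signal is strictly greater than the cutoff value, so the SE set is
#' always a top-k suffix of the ranking.
#'
#' @param peaks a [peak_set].
#' @param track a [signal_track] (raw or RPKM; use one convention per
#'   dataset).
#' @param stitch_distance stitching gap in bp (default 12500).
#' @param control optional control [signal_track] subtracted before
#'   clamping at zero.
#' @param tss_exclusion as in [stitch_peaks].
#' @return An object of class `se_call`: the scored region table (ascending
#'   by signal, with `is_super`), `cutoff_value`, `cutoff_index`,
#'   `scaled_x`, `scaled_y`, and the call parameters.
#' @examples
#' pk <- peak_set("chr1", c(0, 5000, 2e5, 4e5, 6e5), c(1000, 6000, 2.01e5, 4.01e5, 6.01e5))
#' tr <- signal_track(list(chr1 = c(rep(20, 120), rep(1, 13880))), bin_width = 50)
#' fit <- call_superenhancers(pk, tr)
#' summary(fit)
#' @export
call_superenhancers <- function(peaks, track, stitch_distance = 12500,
                                control = NULL, tss_exclusion = NULL) {
  stitched <- stitch_peaks(peaks, stitch_distance, tss_exclusion)
  if (nrow(stitched) == 0) {
    regions <- stitched
    regions$signal <- numeric(0); regions$rank <- integer(0)
    regions$is_super <- logical(0)
    return(structure(list(regions = regions, cutoff_value = 0,
                          cutoff_index = 0L, scaled_x = numeric(0),
                          scaled_y = numeric(0),
                          stitch_distance = stitch_distance,
                          source = attr(peaks, "source"),
                          marker = attr(peaks, "marker")),
                     class = "se_call"))
  }
  scored <- score_stitched(stitched, track, control)
  if (nrow(scored) >= 2) {
    cut <- find_se_cutoff(scored$signal)
  } else {
    # a single region has no curve; conservatively no super-enhancer
    cut <- list(cutoff_value = scored$signal[1], cutoff_index = 1L,
                scaled_x = 0, scaled_y = 1)
  }
  scored$is_super <- scored$signal > cut$cutoff_value
  structure(list(regions = scored, cutoff_value = cut$cutoff_value,
                 cutoff_index = cut$cutoff_index, scaled_x = cut$scaled_x,
                 scaled_y = cut$scaled_y, stitch_distance = stitch_distance,
                 source = attr(peaks, "source"), marker = attr(peaks, "marker")),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat("Super-enhancer call",
      if (!is.null(x$source) && !is.na(x$source)) paste0("(", x$source, ")"),
      "\n")
  cat("  stitched regions:", nrow(x$regions),
      " stitch distance:", x$stitch_distance, "bp\n")
  cat("  cutoff signal:", format(x$cutoff_value, digits = 6),
      " super-enhancers:", sum(x$regions$is_super), "\n")
  invisible(x)
}

#' @export
summary.se_call <- function(object, ...) {
  r <- object$regions
  out <- list(n_regions = nrow(r), n_super = sum(r$is_super),
              n_typical = sum(!r$is_super), cutoff_value = object$cutoff_value,
              top = utils::head(r[order(-r$signal),
                                  c("chrom", "start", "end", "n_constituents",
                                    "signal", "rank", "is_super")], 10))
  class(out) <- "summary.se_call"
  out
}

#' @export
print.summary.se_call <- function(x, ...) {
  cat("Stitched regions:", x$n_regions, "| SE:", x$n_super,
      "| TE:", x$n_typical, "| cutoff:", format(x$cutoff_value, digits = 6),
      "\nTop-ranked regions:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Hockey-stick plot of an SE call
#'
#' Plots regions by ascending rank against signal, with the cutoff marked;
#' super-enhancers are highlighted.
#' @param x an `se_call`.
#' @param ... passed to [graphics::plot].
#' @return `x`, invisibly.
#' @export
plot.se_call <- function(x, ...) {
  r <- x$regions
  n <- nrow(r)
  graphics::plot(seq_len(n), r$signal, type = "p", pch = 16, cex = 0.5,
                 col = ifelse(r$is_super, "red3", "grey40"),
                 xlab = "regions ranked by signal (ascending)",
                 ylab = "integrated signal (value x bp)", ...)
  graphics::abline(h = x$cutoff_value, lty = 2)
  graphics::abline(v = x$cutoff_index, lty = 3, col = "grey60")
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("SE (n=%d)", sum(r$is_super)),
                              sprintf("TE (n=%d)", sum(!r$is_super))),
                   col = c("red3", "grey40"), pch = 16)
  invisible(x)
}

#' Constituent enhancers of a super-enhancer
#'
#' Returns the peaks overlapping the SE interval by at least 1 bp, sorted
#' by start — the decomposition of an SE into its component enhancers
#' (e.g. accessibility peaks).
#'
#' @param se a single-row interval (data frame row or list with chrom,
#'   start, end).
#' @param peaks a [peak_set].
#' @return the overlapping peaks, possibly empty.
#' @export
constituent_enhancers <- function(se, peaks) {
  ov <- overlap_bp(se$chrom[1], se$start[1], se$end[1], peaks)
  out <- peaks[ov >= 1, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SE-call artifacts
#'
#' Emits `<prefix>_stitched.tsv` (chrom, start, end, n_constituents,
#' signal, rank, is_super), `<prefix>_SE.bed` and `<prefix>_TE.bed`
#' (score column = region signal).
#' @param x an `se_call`.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_se_call <- function(x, prefix) {
  r <- x$regions
  tab <- r[, c("chrom", "start", "end", "n_constituents", "signal", "rank",
               "is_super")]
  f1 <- paste0(prefix, "_stitched.tsv")
  utils::write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- function(sub, path) {
    df <- r[sub, , drop = FALSE]
    df$name <- sprintf("%s_%d", basename(prefix), seq_len(nrow(df)))
    df$score <- df$signal
    df$strand <- "*"
    write_intervals(sort_intervals(df), path)
  }
  f2 <- paste0(prefix, "_SE.bed"); bed(r$is_super, f2)
  f3 <- paste0(prefix, "_TE.bed"); bed(!r$is_super, f3)
  invisible(c(f1, f2, f3))
}
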