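# Overlap test used throughout the dynamics module: two regions "match"
# when they share at least max(1 bp, min_overlap_frac x shorter width).
regions_match <- function(a_start, a_end, b_start, b_end, min_overlap_frac) {
  ov <- pmin(a_end, b_end) - pmax(a_start, b_start)
  need <- pmax(1, min_overlap_frac * pmin(a_end - a_start, b_end - b_start))
  ov >= need
}

# index of the matching partner in `others` (same chromosome, best = max
# overlap, ties to smallest start); NA when none matches
best_partner <- function(chrom, start, end, others, min_overlap_frac) {
  same <- which(others$chrom == chrom)
  if (!length(same)) return(NA_integer_)
  o <- others[same, , drop = FALSE]
  hit <- regions_match(start, end, o$start, o$end, min_overlap_frac)
  if (!any(hit)) return(NA_integer_)
  ov <- pmin(end, o$end) - pmax(start, o$start)
  ov[!hit] <- -Inf
  cand <- which(ov == max(ov))
  same[cand[which.min(o$start[cand])]]
}

#' Classify SE dynamics between two conditions
#'
#' Presence/absence comparison of super-enhancer sets between a control and
#' a treated condition. A treated SE is `shared` when some control SE
#' overlaps it by at least `max(1 bp, min_overlap_frac x shorter width)`,
#' otherwise `gain`; control SEs with no such treated partner are `lost`.
#' Swapping the two inputs swaps gain and lost exactly.
#'
#' @param se_control,se_treated interval data frames of SE regions.
#' @param min_overlap_frac minimum overlap as a fraction of the shorter
#'   region, in `[0, 1]`; the default 0 means any 1-bp overlap counts.
#' @return An object of class `se_dynamics` with components `gain`, `lost`,
#'   `shared` (treated-condition representatives), `shared_control`
#'   (their control partners) and `overlap_rule`.
#' @export
classify_dynamics <- function(se_control, se_treated, min_overlap_frac = 0) {
  if (min_overlap_frac < 0 || min_overlap_frac > 1)
    stop("min_overlap_frac must be in [0, 1]", call. = FALSE)
  se_control <- sort_intervals(as.data.frame(se_control))
  se_treated <- sort_intervals(as.data.frame(se_treated))
  nt <- nrow(se_treated); nc <- nrow(se_control)
  t_partner <- vapply(seq_len(nt), function(i)
    best_partner(se_treated$chrom[i], se_treated$start[i], se_treated$end[i],
                 se_control, min_overlap_frac), NA_integer_)
  c_has <- vapply(seq_len(nc), function(i)
    !is.na(best_partner(se_control$chrom[i], se_control$start[i],
                        se_control$end[i], se_treated, min_overlap_frac)),
    logical(1))
  shared_idx <- which(!is.na(t_partner))
  structure(list(
    gain = se_treated[is.na(t_partner), , drop = FALSE],
    lost = se_control[!c_has, , drop = FALSE],
    shared = se_treated[shared_idx, , drop = FALSE],
    shared_control = se_control[t_partner[shared_idx], , drop = FALSE],
    overlap_rule = min_overlap_frac
  ), class = "se_dynamics")
}

#' @export
print.se_dynamics <- function(x, ...) {
  cat("SE dynamics: gain", nrow(x$gain), "| lost", nrow(x$lost),
      "| shared", nrow(x$shared),
      sprintf("(overlap rule: >= max(1 bp, %.2f x shorter))\n",
              x$overlap_rule))
  invisible(x)
}

#' Consensus of gain-SE sets across datasets
#'
#' A gain SE is in the consensus when every dataset has a gain SE
#' overlapping it under the same rule as [classify_dynamics]. For each such
#' region the reported interval is the intersection span of the matched
#' representatives (clamped to the anchoring region when the mutual
#' intersection is empty).
#'
#' @param gain_sets named list (>= 2) of interval data frames, one per
#'   dataset.
#' @param min_overlap_frac overlap rule as in [classify_dynamics].
#' @return An object of class `consensus_result` with `common_regions`
#'   (consensus interval plus per-dataset representative coordinates),
#'   `per_dataset_counts` and `datasets`.
#' @export
consensus_regions <- function(gain_sets, min_overlap_frac = 0) {
  if (length(gain_sets) < 2)
    stop("consensus requires at least 2 datasets", call. = FALSE)
  if (is.null(names(gain_sets)) || any(!nzchar(names(gain_sets))))
    names(gain_sets) <- paste0("dataset", seq_along(gain_sets))
  gain_sets <- lapply(gain_sets, function(g) sort_intervals(as.data.frame(g)))
  anchor <- gain_sets[[1]]
  rows <- list()
  for (i in seq_len(nrow(anchor))) {
    reps <- list(anchor[i, c("chrom", "start", "end"), drop = FALSE])
    ok <- TRUE
    for (d in seq_along(gain_sets)[-1]) {
      j <- best_partner(anchor$chrom[i], anchor$start[i], anchor$end[i],
                        gain_sets[[d]], min_overlap_frac)
      if (is.na(j)) { ok <- FALSE; break }
      reps[[d]] <- gain_sets[[d]][j, c("chrom", "start", "end"), drop = FALSE]
    }
    if (!ok) next
    starts <- vapply(reps, `[[`, 0, "start")
    ends <- vapply(reps, `[[`, 0, "end")
    cs <- max(starts); ce <- min(ends)
    if (cs >= ce) { cs <- anchor$start[i]; ce <- anchor$end[i] }
    row <- data.frame(chrom = anchor$chrom[i], start = cs, end = ce)
    for (d in seq_along(gain_sets)) {
      row[[paste0(names(gain_sets)[d], "_region")]] <-
        sprintf("%s:%.0f-%.0f", reps[[d]]$chrom, reps[[d]]$start, reps[[d]]$end)
    }
    rows[[length(rows) + 1]] <- row
  }
  common <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  common <- common[!duplicated(common[, c("chrom", "start", "end")]), ,
                   drop = FALSE]
  common <- sort_intervals(common)
  rownames(common) <- NULL
  structure(list(datasets = names(gain_sets),
                 common_regions = common,
                 per_dataset_counts = vapply(gain_sets, nrow, 0L),
                 common_genes = NULL,
                 overlap_rule = min_overlap_frac),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus over", length(x$datasets), "datasets:",
      nrow(x$common_regions), "common region(s)\n")
  cat("  per-dataset gain counts:",
      paste(sprintf("%s=%d", x$datasets, x$per_dataset_counts),
            collapse = ", "), "\n")
  if (nrow(x$common_regions))
    print(x$common_regions[, c("chrom", "start", "end")], row.names = FALSE)
  if (!is.null(x$common_genes))
    cat("  common genes:", paste(x$common_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Annotate regions to nearest TSS
#'
#' Assigns each region the gene whose strand-aware transcription start site
#' (`start` on +, `end - 1` on -) is nearest to the region center
#' (`floor((start + end) / 2)`), restricted to the region's chromosome.
#' Ties go to the smaller TSS coordinate, then lexicographic gene id. The
#' reported distance is 0 when the center lies inside the assigned gene
#' body, else the absolute center-to-TSS distance.
#'
#' @param regions interval data frame.
#' @param genes gene model from [read_gene_model] (must be non-empty).
#' @return data frame: region coordinates, `gene_id`, `distance`. Regions
#'   on chromosomes absent from the gene model get `NA` with a warning.
#' @export
annotate_nearest_tss <- function(regions, genes) {
  if (is.null(genes) || nrow(genes) == 0)
    stop("empty gene model", call. = FALSE)
  regions <- as.data.frame(regions)
  n <- nrow(regions)
  gene_id <- character(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    center <- floor((regions$start[i] + regions$end[i]) / 2)
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (!nrow(g)) {
      gene_id[i] <- NA_character_; dist[i] <- NA_real_
      next
    }
    dd <- abs(g$tss - center)
    cand <- which(dd == min(dd))
    if (length(cand) > 1) {
      cand <- cand[order(g$tss[cand], g$gene_id[cand])]
    }
    k <- cand[1]
    gene_id[i] <- g$gene_id[k]
    dist[i] <- if (center >= g$start[k] && center < g$end[k]) 0 else dd[k]
  }
  if (anyNA(gene_id))
    warning("region(s) on chromosome(s) absent from the gene model ",
            "assigned NA", call. = FALSE)
  out <- regions[, c("chrom", "start", "end"), drop = FALSE]
  out$gene_id <- gene_id
  out$distance <- dist
  rownames(out) <- NULL
  out
}
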