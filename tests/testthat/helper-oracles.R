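# Independent brute-force oracles used to verify the package's algorithms.
# Each is deliberately written by a different route than the implementation.

# Slope-1 cutoff by explicit scan over the scaled curve, ties to the
# largest index.
oracle_cutoff <- function(s) {
  n <- length(s)
  stopifnot(n >= 2)
  s <- pmax(s, 0)
  if (max(s) == 0) return(list(cutoff_value = 0, cutoff_index = n))
  best_d <- Inf
  best_i <- NA_integer_
  for (i in seq_len(n)) {
    x <- (i - 1) / (n - 1)
    y <- s[i] / max(s)
    d <- y - x
    if (d <= best_d) {           # <=: later index wins on ties
      best_d <- d
      best_i <- i
    }
  }
  list(cutoff_value = s[best_i], cutoff_index = best_i)
}

# Transitive gap-merge by painting each peak padded by the stitch distance
# onto a base-resolution vector and reading off connected components --
# a different mechanism than the sorted single-pass implementation.
oracle_stitch <- function(peaks, d) {
  out <- list()
  for (chr in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    lim <- max(p$end) + d + 2
    painted <- logical(lim)
    for (i in seq_len(nrow(p)))
      painted[(p$start[i] + 1):(p$end[i] + d)] <- TRUE
    r <- rle(painted)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    comp_s <- starts[r$values] - 1      # back to 0-based
    comp_e <- ends[r$values]
    for (k in seq_along(comp_s)) {
      member <- p$start >= comp_s[k] & p$start < comp_e[k]
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = min(p$start[member]), end = max(p$end[member]),
        n_constituents = sum(member))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Benjamini-Hochberg by the definitional min over j >= i of p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(n), function(i)
    min(1, min(ps[i:n] * n / (i:n))), 0)
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# Per-base integration of a binned track over [start, end).
oracle_region_area <- function(bins, w, start, end) {
  total <- 0
  for (pos in seq(start, end - 1)) {
    b <- floor(pos / w) + 1
    if (b >= 1 && b <= length(bins)) total <- total + bins[b]
  }
  total
}

# All-pairs presence/absence classification of two SE sets.
oracle_classify <- function(ctrl, trt, f) {
  match_pair <- function(a, b) {
    if (a$chrom != b$chrom) return(FALSE)
    ov <- min(a$end, b$end) - max(a$start, b$start)
    ov >= max(1, f * min(a$end - a$start, b$end - b$start))
  }
  t_shared <- vapply(seq_len(nrow(trt)), function(i)
    any(vapply(seq_len(nrow(ctrl)), function(j)
      match_pair(trt[i, ], ctrl[j, ]), logical(1))), logical(1))
  c_shared <- vapply(seq_len(nrow(ctrl)), function(j)
    any(vapply(seq_len(nrow(trt)), function(i)
      match_pair(trt[i, ], ctrl[j, ]), logical(1))), logical(1))
  list(gain = trt[!t_shared, , drop = FALSE],
       lost = ctrl[!c_shared, , drop = FALSE],
       shared = trt[t_shared, , drop = FALSE])
}
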