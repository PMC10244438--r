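#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of p-values, returned in the
#' input order (a thin wrapper over [stats::p.adjust] with input
#' validation, provided so DEG tables carrying only p-values can be
#' brought under a Q-value cutoff).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted q-values in `[0, 1]`, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter a DEG table into up/down gene sets
#'
#' Applies the conventional thresholds inclusively: up = log2fc >=
#' `min_abs_log2fc` and q <= `max_q`; down = log2fc <= `-min_abs_log2fc`
#' and q <= `max_q`.
#'
#' @param records DEG data frame from [read_deg_table]; every row must
#'   carry a q-value (run [bh_adjust] on the p-values first if not).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1).
#' @param max_q maximum q-value (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
filter_degs <- function(records, min_abs_log2fc = 1, max_q = 0.05) {
  if (any(is.na(records$qvalue)))
    stop("DEG records with missing q-values; run bh_adjust on the ",
         "p-values first", call. = FALSE)
  list(up = records$gene_id[records$log2fc >= min_abs_log2fc &
                              records$qvalue <= max_q],
       down = records$gene_id[records$log2fc <= -min_abs_log2fc &
                                records$qvalue <= max_q])
}

#' Fill missing q-values in a DEG table
#'
#' Rows with a q-value keep it; the remaining rows get Benjamini-Hochberg
#' adjusted p-values computed over all p-values in the table.
#' @param records DEG data frame.
#' @return the table with `qvalue` complete.
#' @export
ensure_qvalues <- function(records) {
  miss <- is.na(records$qvalue)
  if (!any(miss)) return(records)
  if (any(is.na(records$pvalue[miss])))
    stop("DEG rows with neither p-value nor q-value", call. = FALSE)
  q <- bh_adjust(records$pvalue)
  records$qvalue[miss] <- q[miss]
  records
}

#' Intersect SE target genes with DEG sets
#'
#' The nomination step: candidates are the genes present in all three sets
#' — SE-associated genes, upregulated DEGs, and the disease DEG list.
#' Matching is exact and case-sensitive; identifiers that would match only
#' after upper-casing trigger a warning (set `harmonize_case = TRUE` to
#' upper-case all sets first).
#'
#' @param se_genes,up_genes,disease_genes character vectors of gene ids.
#' @param harmonize_case upper-case all identifiers before intersecting.
#' @return An object of class `candidate_report`: sorted `candidates`, the
#'   three input sets, and a `provenance` list of set sizes.
#' @export
intersect_candidates <- function(se_genes, up_genes, disease_genes,
                                 harmonize_case = FALSE) {
  sets <- list(se_genes = unique(as.character(se_genes)),
               up_genes = unique(as.character(up_genes)),
               disease_genes = unique(as.character(disease_genes)))
  if (harmonize_case) {
    sets <- lapply(sets, toupper)
    sets <- lapply(sets, unique)
  } else {
    exact <- Reduce(intersect, sets)
    loose <- Reduce(intersect, lapply(sets, toupper))
    if (length(setdiff(loose, toupper(exact))))
      warning("gene identifiers differing only by case across sets: ",
              paste(utils::head(setdiff(loose, toupper(exact)), 5),
                    collapse = ", "),
              " (use harmonize_case = TRUE to match them)", call. = FALSE)
  }
  candidates <- sort(Reduce(intersect, sets))
  structure(list(candidates = candidates,
                 se_genes = sets$se_genes, up_genes = sets$up_genes,
                 disease_genes = sets$disease_genes,
                 provenance = list(n_se_genes = length(sets$se_genes),
                                   n_up_genes = length(sets$up_genes),
                                   n_disease_genes = length(sets$disease_genes),
                                   n_candidates = length(candidates),
                                   harmonize_case = harmonize_case)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  p <- x$provenance
  cat("Candidate nomination: |SE genes| =", p$n_se_genes,
      "| |up DEGs| =", p$n_up_genes,
      "| |disease DEGs| =", p$n_disease_genes, "\n")
  cat("Triple intersection (", p$n_candidates, "):",
      paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}
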