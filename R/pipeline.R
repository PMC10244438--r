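#' Read and validate a pipeline configuration
#'
#' YAML configuration listing the datasets (each a control/treated pair of
#' peak and coverage files), the gene model, the DEG table, the disease
#' gene list and the analysis parameters. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path YAML file.
#' @return validated config list with absolute paths.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  validate_pipeline_config(cfg, base)
}

validate_pipeline_config <- function(cfg, base = ".") {
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  defaults <- list(stitch_distance = 12500, bin_width = 50,
                   min_overlap_frac = 0,
                   tss_exclusion = list(enabled = FALSE, window = 2500),
                   venn_mode = "interval", output_dir = "results", seed = 1L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    stop("config must list at least one dataset", call. = FALSE)
  if (cfg$stitch_distance < 0 || cfg$bin_width < 1)
    stop("config thresholds must be positive", call. = FALSE)
  if (!cfg$venn_mode %in% c("interval", "gene"))
    stop("venn_mode must be 'interval' or 'gene'", call. = FALSE)
  for (i in seq_along(cfg$datasets)) {
    ds <- cfg$datasets[[i]]
    if (is.null(ds$name)) ds$name <- paste0("dataset", i)
    for (cond in c("control", "treated")) {
      if (is.null(ds[[cond]]$peaks) || is.null(ds[[cond]]$signal))
        stop("dataset '", ds$name, "' lacks ", cond, " peaks/signal paths",
             call. = FALSE)
      for (what in c("peaks", "signal", "control_signal")) {
        p <- ds[[cond]][[what]]
        if (is.null(p)) next
        p <- resolve(p)
        if (!file.exists(p))
          stop("dataset '", ds$name, "': missing ", cond, " ", what,
               " file: ", p, call. = FALSE)
        ds[[cond]][[what]] <- p
      }
    }
    cfg$datasets[[i]] <- ds
  }
  if (is.null(cfg$deg) || is.null(cfg$deg$table))
    stop("config must name a DEG table under deg: table:", call. = FALSE)
  if (is.null(cfg$deg$lfc_min)) cfg$deg$lfc_min <- 1
  if (is.null(cfg$deg$q_max)) cfg$deg$q_max <- 0.05
  for (nm in c("disease_genes", "gene_model")) {
    if (is.null(cfg[[nm]])) stop("config must name ", nm, call. = FALSE)
    cfg[[nm]] <- resolve(cfg[[nm]])
    if (!file.exists(cfg[[nm]]))
      stop("missing ", nm, " file: ", cfg[[nm]], call. = FALSE)
  }
  cfg$deg$table <- resolve(cfg$deg$table)
  if (!file.exists(cfg$deg$table))
    stop("missing DEG table: ", cfg$deg$table, call. = FALSE)
  cfg$output_dir <- resolve(cfg$output_dir)
  cfg
}

#' Run the end-to-end SE consensus pipeline
#'
#' For every dataset, calls super-enhancers in both conditions and
#' classifies gain/lost/shared dynamics; intersects the gain sets across
#' datasets into a consensus; annotates regions to nearest TSS; filters the
#' DEG table by the |log2fc| and Q cutoffs; and intersects SE target genes
#' with the upregulated and disease gene sets to nominate candidates. All
#' artifacts (SE tables and BEDs, gain/lost/shared BEDs, consensus and
#' candidate TSVs, `report.json`, `run.log`) are written under the
#' configured output directory.
#'
#' @param config a config list, or path to a YAML file (see
#'   [read_pipeline_config]).
#' @param plots attempt PNG hockey-stick plots (skipped with a warning if
#'   no graphics device is available).
#' @return An object of class `pipeline_report` (also written as
#'   `report.json`), invisibly.
#' @export
run_pipeline <- function(config, plots = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- validate_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO ",
                   paste0(...))
    cat(line, "\n", file = stderr())
    cat(line, "\n", file = logf, append = TRUE)
  }
  report <- list(tool = "seconsensus",
                 version = as.character(utils::packageVersion("seconsensus")),
                 status = "FAILED", parameters = list(
                   stitch_distance = config$stitch_distance,
                   bin_width = config$bin_width,
                   min_overlap_frac = config$min_overlap_frac,
                   tss_exclusion = config$tss_exclusion,
                   deg = config$deg, venn_mode = config$venn_mode))
  finish <- function() {
    report$timestamp <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result <- tryCatch({
    logmsg("parameters: stitch_distance=", config$stitch_distance,
           " min_overlap_frac=", config$min_overlap_frac,
           " lfc_min=", config$deg$lfc_min, " q_max=", config$deg$q_max,
           " venn_mode=", config$venn_mode)
    genes <- read_gene_model(config$gene_model)
    logmsg("gene model: ", nrow(genes), " genes")

    inputs <- character(0)
    per_dataset <- list()
    gain_sets <- list(); lost_sets <- list()
    for (ds in config$datasets) {
      t0 <- proc.time()[["elapsed"]]
      calls <- list()
      for (cond in c("control", "treated")) {
        pk <- read_intervals(ds[[cond]]$peaks, source = ds$name,
                             marker = ds$marker)
        tr <- read_signal_track(ds[[cond]]$signal, bin_width = config$bin_width)
        ctrl <- if (!is.null(ds[[cond]]$control_signal))
          read_signal_track(ds[[cond]]$control_signal,
                            bin_width = config$bin_width) else NULL
        tex <- if (isTRUE(config$tss_exclusion$enabled))
          list(genes = genes, window = config$tss_exclusion$window) else NULL
        calls[[cond]] <- call_superenhancers(
          pk, tr, stitch_distance = config$stitch_distance,
          control = ctrl, tss_exclusion = tex)
        write_se_call(calls[[cond]],
                      file.path(out, paste0(ds$name, "_", cond)))
        inputs <- c(inputs, ds[[cond]]$peaks, ds[[cond]]$signal)
        logmsg(ds$name, " ", cond, ": ", nrow(calls[[cond]]$regions),
               " stitched regions, ", sum(calls[[cond]]$regions$is_super),
               " SE")
        if (plots) {
          ok <- tryCatch({
            grDevices::png(file.path(out, paste0(ds$name, "_", cond,
                                                 "_hockey.png")),
                           width = 700, height = 500)
            plot(calls[[cond]], main = paste(ds$name, cond))
            grDevices::dev.off()
            TRUE
          }, error = function(e) FALSE)
          if (!ok) logmsg("WARN plot skipped for ", ds$name, " ", cond,
                          " (no graphics device)")
        }
      }
      se_of <- function(cl) cl$regions[cl$regions$is_super, , drop = FALSE]
      dyn <- classify_dynamics(se_of(calls$control), se_of(calls$treated),
                               min_overlap_frac = config$min_overlap_frac)
      for (slot in c("gain", "lost", "shared"))
        write_intervals(dyn[[slot]],
                        file.path(out, paste0(ds$name, "_", slot, ".bed")))
      gain_sets[[ds$name]] <- dyn$gain
      lost_sets[[ds$name]] <- dyn$lost
      per_dataset[[ds$name]] <- list(
        marker = ds$marker,
        n_stitched_control = nrow(calls$control$regions),
        n_stitched_treated = nrow(calls$treated$regions),
        n_se_control = sum(calls$control$regions$is_super),
        n_se_treated = sum(calls$treated$regions$is_super),
        n_gain = nrow(dyn$gain), n_lost = nrow(dyn$lost),
        n_shared = nrow(dyn$shared),
        wall_s = round(proc.time()[["elapsed"]] - t0, 2))
      logmsg(ds$name, ": gain=", nrow(dyn$gain), " lost=", nrow(dyn$lost),
             " shared=", nrow(dyn$shared))
    }

    # cross-dataset consensus of gain sets (a single dataset is its own
    # consensus)
    cons <- if (length(gain_sets) >= 2)
      consensus_regions(gain_sets, min_overlap_frac = config$min_overlap_frac)
    else structure(list(datasets = names(gain_sets),
                        common_regions = gain_sets[[1]],
                        per_dataset_counts = vapply(gain_sets, nrow, 0L),
                        common_genes = NULL,
                        overlap_rule = config$min_overlap_frac),
                   class = "consensus_result")
    cons_ann <- if (nrow(cons$common_regions))
      annotate_nearest_tss(cons$common_regions, genes)
    else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    gene_id = character(), distance = numeric())
    cons$common_genes <- sort(unique(stats::na.omit(cons_ann$gene_id)))
    logmsg("consensus: ", nrow(cons$common_regions), " region(s), genes: ",
           paste(cons$common_genes, collapse = ","))

    # SE gene set for the nomination step: interval-level consensus genes,
    # or intersection of per-dataset gain gene sets in gene mode
    se_genes <- if (config$venn_mode == "gene" && length(gain_sets) >= 2) {
      sets <- lapply(gain_sets, function(g)
        if (nrow(g)) unique(stats::na.omit(annotate_nearest_tss(g, genes)$gene_id))
        else character(0))
      sort(Reduce(intersect, sets))
    } else cons$common_genes

    deg <- ensure_qvalues(read_deg_table(config$deg$table))
    sets <- filter_degs(deg, min_abs_log2fc = config$deg$lfc_min,
                        max_q = config$deg$q_max)
    disease <- read_gene_list(config$disease_genes)
    logmsg("DEG: ", length(sets$up), " up, ", length(sets$down),
           " down of ", nrow(deg), "; disease list: ", length(disease))
    cand <- intersect_candidates(se_genes, sets$up, disease)
    logmsg("candidates: ", paste(cand$candidates, collapse = ",") )

    cons_tab <- cons_ann
    if (nrow(cons$common_regions) && ncol(cons$common_regions) > 3) {
      extra <- cons$common_regions[, setdiff(names(cons$common_regions),
                                             c("chrom", "start", "end")),
                                   drop = FALSE]
      cons_tab <- cbind(cons_ann, extra)
    }
    utils::write.table(cons_tab, file.path(out, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cand_tab <- data.frame(gene = cand$candidates)
    if (nrow(cand_tab)) {
      m <- match(cand_tab$gene, deg$gene_id)
      cand_tab$log2fc <- deg$log2fc[m]
      cand_tab$qvalue <- deg$qvalue[m]
      cand_tab$se_region <- vapply(cand_tab$gene, function(g) {
        hit <- cons_ann$gene_id == g & !is.na(cons_ann$gene_id)
        if (any(hit)) sprintf("%s:%.0f-%.0f", cons_ann$chrom[hit][1],
                              cons_ann$start[hit][1], cons_ann$end[hit][1])
        else NA_character_
      }, "")
    }
    utils::write.table(cand_tab, file.path(out, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # aggregation views of the differential counts: per dataset, raw
    # union, and overlap-deduplicated union
    dedup <- function(sets) {
      all <- do.call(rbind, lapply(sets, function(s)
        s[, c("chrom", "start", "end"), drop = FALSE]))
      if (is.null(all) || !nrow(all)) return(0L)
      nrow(stitch_peaks(peak_set(all$chrom, all$start, all$end),
                        stitch_distance = 0))
    }
    report$datasets <- per_dataset
    report$gain <- list(per_dataset = as.list(vapply(gain_sets, nrow, 0L)),
                        union = sum(vapply(gain_sets, nrow, 0L)),
                        union_dedup = dedup(gain_sets))
    report$lost <- list(per_dataset = as.list(vapply(lost_sets, nrow, 0L)),
                        union = sum(vapply(lost_sets, nrow, 0L)),
                        union_dedup = dedup(lost_sets))
    report$consensus <- list(n = nrow(cons$common_regions),
                             loci = if (nrow(cons$common_regions))
                               sprintf("%s:%.0f-%.0f",
                                       cons$common_regions$chrom,
                                       cons$common_regions$start,
                                       cons$common_regions$end)
                             else character(0),
                             genes = cons$common_genes)
    report$deg <- list(n_total = nrow(deg), n_up = length(sets$up),
                       n_down = length(sets$down))
    report$candidates <- cand$candidates
    report$candidate_provenance <- cand$provenance
    report$input_checksums <- as.list(tools::md5sum(unique(c(
      inputs, config$deg$table, config$disease_genes, config$gene_model))))

    # self-consistency audit: counts in the report must equal the records
    # in the emitted files
    audit_ok <- TRUE
    for (nm in names(gain_sets)) {
      for (slot in c("gain", "lost")) {
        f <- file.path(out, paste0(nm, "_", slot, ".bed"))
        n_file <- nrow(read_intervals(f))
        n_rep <- report[[slot]]$per_dataset[[nm]]
        if (n_file != n_rep) audit_ok <- FALSE
      }
    }
    cand_file <- utils::read.table(file.path(out, "candidates.tsv"),
                                   header = TRUE, sep = "\t")
    if (nrow(cand_file) != length(cand$candidates)) audit_ok <- FALSE
    report$audit <- list(ok = audit_ok)
    if (!audit_ok) stop("self-consistency audit failed", call. = FALSE)
    logmsg("audit: ok")
    report$status <- "OK"
    finish()
    structure(report, class = "pipeline_report")
  }, error = function(e) {
    report$error <<- conditionMessage(e)
    finish()
    stop(e)
  })
  invisible(result)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (", x$status, "), ", length(x$datasets),
      " dataset(s)\n", sep = "")
  for (nm in names(x$datasets)) {
    d <- x$datasets[[nm]]
    cat(sprintf("  %s: SE ctrl/treat %d/%d, gain %d, lost %d, shared %d\n",
                nm, d$n_se_control, d$n_se_treated, d$n_gain, d$n_lost,
                d$n_shared))
  }
  cat("  consensus:", x$consensus$n, "region(s);",
      "genes:", paste(x$consensus$genes, collapse = ","), "\n")
  cat("  DEG up/down:", x$deg$n_up, "/", x$deg$n_down, "\n")
  cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Precision and recall of called SEs against planted loci
#'
#' A called region counts as a true positive when it overlaps any truth
#' locus by >= 1 bp; recall is the fraction of truth loci overlapped by
#' any called region.
#'
#' @param called interval data frame of called SE regions.
#' @param truth interval data frame of planted loci.
#' @return list with `precision`, `recall`, `n_called`, `n_truth`.
#' @export
recovery_stats <- function(called, truth) {
  called <- as.data.frame(called); truth <- as.data.frame(truth)
  hit_called <- vapply(seq_len(nrow(called)), function(i)
    any(overlap_bp(called$chrom[i], called$start[i], called$end[i],
                   truth) >= 1), logical(1))
  hit_truth <- vapply(seq_len(nrow(truth)), function(i)
    any(overlap_bp(truth$chrom[i], truth$start[i], truth$end[i],
                   called) >= 1), logical(1))
  list(precision = if (nrow(called)) mean(hit_called) else NA_real_,
       recall = if (nrow(truth)) mean(hit_truth) else NA_real_,
       n_called = nrow(called), n_truth = nrow(truth))
}
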