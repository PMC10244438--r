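#' Simulation parameters for a synthetic multi-dataset SE study
#'
#' Defaults describe a two-condition (control vs osteogenic-induction style)
#' study with five (cell line, marker) datasets on a small two-chromosome
#' pseudo-genome: one gain SE planted in every dataset's treated condition
#' (the consensus locus), plus per-dataset private-gain, lost and
#' constitutive SEs, singleton background enhancers, boxcar coverage bumps
#' with truncated Gaussian noise, and a DEG table in which gain-SE target
#' genes are upregulated.
#'
#' @param seed RNG seed; identical seeds give identical studies.
#' @param n_chroms,chrom_length genome shape.
#' @param bin_width coverage bin width in bp.
#' @param n_genes genes placed without overlap.
#' @param n_datasets datasets (cell line x marker pairs).
#' @param n_shared_gain_se gain SEs planted in every dataset (treated only).
#' @param n_private_gain_se,n_lost_se,n_constitutive_se per-dataset counts.
#' @param constituents_per_se,constituent_length,constituent_gap geometry of
#'   each planted SE; the gap must not exceed `stitch_distance` so the
#'   constituents stitch into one region.
#' @param n_background_peaks isolated singleton enhancers (typical
#'   enhancers) per dataset/condition.
#' @param amp_se,amp_te boxcar amplitudes for SE constituents and
#'   background peaks (`amp_se > amp_te > 0`).
#' @param noise_sd sd of the zero-truncated Gaussian coverage noise.
#' @param deg_effect_mean,deg_effect_sd log2 fold change distribution of
#'   gain-SE target genes.
#' @param background_lfc_sd log2 fold change spread of null genes.
#' @param n_disease_decoys extra genes added to the disease list.
#' @param stitch_distance stitching distance the study is built for; also
#'   the minimum separation between independent features.
#' @param library_size nominal mapped-read count stored on each track.
#' @return a `se_sim_params` list.
#' @export
se_sim_params <- function(seed = 42L, n_chroms = 2, chrom_length = 1e7,
                          bin_width = 50, n_genes = 200, n_datasets = 5,
                          n_shared_gain_se = 1, n_private_gain_se = 3,
                          n_lost_se = 3, n_constitutive_se = 5,
                          constituents_per_se = 4, constituent_length = 1200,
                          constituent_gap = 1800, n_background_peaks = 200,
                          amp_se = 20, amp_te = 2, noise_sd = 1,
                          deg_effect_mean = 3, deg_effect_sd = 0.5,
                          background_lfc_sd = 0.3, n_disease_decoys = 30,
                          stitch_distance = 12500, library_size = 2e7) {
  p <- as.list(environment())
  counts <- c(p$n_chroms, p$n_genes, p$n_datasets, p$n_shared_gain_se,
              p$n_private_gain_se, p$n_lost_se, p$n_constitutive_se,
              p$n_background_peaks, p$n_disease_decoys)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!(p$amp_se > p$amp_te && p$amp_te > 0))
    stop("need amp_se > amp_te > 0", call. = FALSE)
  if (p$constituent_gap > p$stitch_distance)
    stop("constituent_gap exceeds stitch_distance: planted constituents ",
         "would not stitch into one region", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  class(p) <- "se_sim_params"
  p
}

# default (cell line, marker) labels, recycled as needed
dataset_labels <- function(n) {
  base <- data.frame(
    name = c("lineA_H3K27ac", "lineB_H3K27ac", "lineB_BRD4",
             "lineC_H3K27ac", "lineC_MED1"),
    marker = c("H3K27ac", "H3K27ac", "BRD4", "H3K27ac", "MED1"))
  idx <- ((seq_len(n) - 1) %% nrow(base)) + 1
  out <- base[idx, , drop = FALSE]
  out$name <- make.unique(out$name, sep = "_rep")
  rownames(out) <- NULL
  out
}

#' Simulate a synthetic SE study with planted ground truth
#'
#' Lays genes and enhancer features out on a slot grid so that distinct
#' features are separated by more than the stitch distance, plants SE
#' constituent clusters (boxcar coverage bumps of amplitude `amp_se`)
#' at the TSS of their target genes, singleton background enhancers
#' (amplitude `amp_te`, varying lengths) elsewhere, adds zero-truncated
#' Gaussian noise to every coverage bin, and writes a DEG table in which
#' gain-SE targets are upregulated with tiny p-values while null genes are
#' centred on zero.
#'
#' @param params a [se_sim_params] list.
#' @return An object of class `synthetic_study`: `gene_model`, `datasets`
#'   (per dataset: `control`/`treated`, each with `peaks` and `track`),
#'   `deg_table`, `disease_genes`, and `truth` (planted SE loci with
#'   labels, target genes, per-gene DE status).
#' @export
simulate_study <- function(params = se_sim_params()) {
  p <- params
  set.seed(p$seed)
  align <- function(x) floor(x / p$bin_width) * p$bin_width
  se_span <- p$constituents_per_se * p$constituent_length +
    (p$constituents_per_se - 1) * p$constituent_gap
  slot_width <- align(max(45000, se_span + 2 * p$stitch_distance + 10000))
  per_chrom <- floor(p$chrom_length / slot_width)
  n_slots <- p$n_chroms * per_chrom
  need <- p$n_genes + p$n_background_peaks
  if (n_slots < need)
    stop("genome too small: need ", need, " feature slots of ", slot_width,
         " bp but only ", n_slots, " fit; increase chrom_length to at least ",
         ceiling(need / p$n_chroms) * slot_width, call. = FALSE)
  n_se_loci <- p$n_shared_gain_se +
    p$n_datasets * (p$n_private_gain_se + p$n_lost_se + p$n_constitutive_se)
  if (n_se_loci > p$n_genes)
    stop("need at least ", n_se_loci, " genes to host ", n_se_loci,
         " planted SE loci", call. = FALSE)

  chroms <- sprintf("chr%d", seq_len(p$n_chroms))
  slot_chrom <- rep(chroms, each = per_chrom)
  slot_start <- rep((seq_len(per_chrom) - 1) * slot_width, times = p$n_chroms)
  pick <- sample.int(n_slots, need)
  gene_slots <- pick[seq_len(p$n_genes)]
  bg_slots <- pick[p$n_genes + seq_len(p$n_background_peaks)]

  # gene bodies of 5 kb in the middle of their slot, strands alternating
  strand <- rep(c("+", "-"), length.out = p$n_genes)
  g_start <- slot_start[gene_slots] + align(slot_width / 2 - 2500)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(p$n_genes)),
    chrom = slot_chrom[gene_slots],
    start = g_start, end = g_start + 5000, strand = strand)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)

  # assign planted SE roles to distinct target genes
  targets <- sample.int(p$n_genes, n_se_loci)
  labels <- dataset_labels(p$n_datasets)
  roles <- data.frame(gene_idx = targets,
                      label = character(n_se_loci),
                      dataset = NA_character_)
  k <- 0
  if (p$n_shared_gain_se) {
    roles$label[k + seq_len(p$n_shared_gain_se)] <- "shared-gain"
    k <- k + p$n_shared_gain_se
  }
  for (d in seq_len(p$n_datasets)) {
    for (lab in c("private-gain", "lost", "constitutive")) {
      cnt <- switch(lab, `private-gain` = p$n_private_gain_se,
                    lost = p$n_lost_se, constitutive = p$n_constitutive_se)
      if (cnt) {
        roles$label[k + seq_len(cnt)] <- lab
        roles$dataset[k + seq_len(cnt)] <- labels$name[d]
        k <- k + cnt
      }
    }
  }

  # constituent peaks of each planted SE, centred on the target TSS
  se_peaks <- lapply(seq_len(n_se_loci), function(i) {
    g <- genes[roles$gene_idx[i], ]
    s0 <- align(g$tss - se_span / 2)
    starts <- s0 + (seq_len(p$constituents_per_se) - 1) *
      (p$constituent_length + p$constituent_gap)
    data.frame(chrom = g$chrom, start = starts,
               end = starts + p$constituent_length,
               name = sprintf("%s_c%d", roles$label[i],
                              seq_len(p$constituents_per_se)))
  })
  truth_loci <- data.frame(
    label = roles$label, dataset = roles$dataset,
    gene_id = genes$gene_id[roles$gene_idx],
    chrom = vapply(se_peaks, function(x) x$chrom[1], ""),
    start = vapply(se_peaks, function(x) min(x$start), 0),
    end = vapply(se_peaks, function(x) max(x$end), 0))

  # isolated singleton background enhancers with varying lengths
  bg_len <- align(sample(seq(600, 2000, by = 50), p$n_background_peaks,
                         replace = TRUE))
  bg_start <- slot_start[bg_slots] + align(slot_width / 2 - 2500)
  background <- data.frame(chrom = slot_chrom[bg_slots], start = bg_start,
                           end = bg_start + bg_len,
                           name = sprintf("bg%04d", seq_len(p$n_background_peaks)))

  n_bins <- ceiling(p$chrom_length / p$bin_width)
  bump <- function(bins, pk, amp) {
    for (j in seq_len(nrow(pk))) {
      b0 <- pk$start[j] / p$bin_width + 1
      b1 <- pk$end[j] / p$bin_width
      bins[[pk$chrom[j]]][b0:b1] <- bins[[pk$chrom[j]]][b0:b1] + amp
    }
    bins
  }
  make_condition <- function(se_idx) {
    pk_se <- if (length(se_idx)) do.call(rbind, se_peaks[se_idx]) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character())
    peaks_df <- rbind(pk_se, background)
    bins <- stats::setNames(lapply(chroms, function(.) numeric(n_bins)), chroms)
    if (nrow(pk_se)) bins <- bump(bins, pk_se, p$amp_se)
    bins <- bump(bins, background, p$amp_te)
    if (p$noise_sd > 0) {
      bins <- lapply(bins, function(v)
        pmax(0, v + stats::rnorm(length(v), 0, p$noise_sd)))
    }
    list(peaks = peak_set(peaks_df$chrom, peaks_df$start, peaks_df$end,
                          name = peaks_df$name),
         track = signal_track(bins, bin_width = p$bin_width,
                              library_size = p$library_size))
  }
  datasets <- vector("list", p$n_datasets)
  for (d in seq_len(p$n_datasets)) {
    own <- roles$dataset == labels$name[d] & !is.na(roles$dataset)
    ctrl_idx <- which(own & roles$label %in% c("lost", "constitutive"))
    trt_idx <- c(which(roles$label == "shared-gain"),
                 which(own & roles$label %in% c("private-gain", "constitutive")))
    ds <- list(name = labels$name[d], marker = labels$marker[d],
               control = make_condition(ctrl_idx),
               treated = make_condition(trt_idx))
    attr(ds$control$peaks, "source") <- labels$name[d]
    attr(ds$treated$peaks, "source") <- labels$name[d]
    attr(ds$control$peaks, "marker") <- labels$marker[d]
    attr(ds$treated$peaks, "marker") <- labels$marker[d]
    datasets[[d]] <- ds
  }
  names(datasets) <- labels$name

  gain_targets <- unique(truth_loci$gene_id[truth_loci$label %in%
                                              c("shared-gain", "private-gain")])
  shared_targets <- unique(truth_loci$gene_id[truth_loci$label == "shared-gain"])
  is_up <- genes$gene_id %in% gain_targets
  lfc <- ifelse(is_up,
                stats::rnorm(p$n_genes, p$deg_effect_mean, p$deg_effect_sd),
                stats::rnorm(p$n_genes, 0, p$background_lfc_sd))
  pval <- ifelse(is_up, 10^-stats::runif(p$n_genes, 8, 20),
                 stats::runif(p$n_genes))
  deg <- data.frame(gene_id = genes$gene_id, log2fc = lfc, pvalue = pval,
                    qvalue = NA_real_, stringsAsFactors = FALSE)

  decoy_pool <- setdiff(genes$gene_id, gain_targets)
  disease <- sort(c(shared_targets,
                    sample(decoy_pool, min(p$n_disease_decoys,
                                           length(decoy_pool)))))

  structure(list(
    params = p, gene_model = genes, datasets = datasets, deg_table = deg,
    disease_genes = disease,
    truth = list(se_loci = truth_loci, gain_targets = gain_targets,
                 shared_gain_targets = shared_targets,
                 de_status = data.frame(gene_id = genes$gene_id,
                                        true_up = is_up))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic SE study:", length(x$datasets), "dataset(s),",
      nrow(x$gene_model), "genes,", nrow(x$truth$se_loci),
      "planted SE loci (seed", x$params$seed, ")\n")
  print(table(x$truth$se_loci$label))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits per-dataset/condition BED peaks and bedGraph coverage, the gene
#' model TSV, the DEG TSV, the disease gene list, the planted truth as
#' JSON, and a ready-to-run pipeline `config.yaml`, plus a manifest of
#' every file with its MD5 checksum.
#'
#' @param study a [simulate_study] result.
#' @param out_dir output directory (created if needed).
#' @return data frame manifest (file, md5, bytes), invisibly; also written
#'   as `manifest.tsv`.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  files <- character(0)
  add <- function(f) files[[length(files) + 1]] <<- f

  gm <- file.path(out_dir, "genes.tsv")
  utils::write.table(study$gene_model[, c("gene_id", "chrom", "start", "end",
                                          "strand")],
                     gm, sep = "\t", quote = FALSE, row.names = FALSE)
  add(gm)
  ds_cfg <- list()
  for (ds in study$datasets) {
    for (cond in c("control", "treated")) {
      pb <- file.path(out_dir, sprintf("%s_%s_peaks.bed", ds$name, cond))
      write_intervals(ds[[cond]]$peaks, pb); add(pb)
      cb <- file.path(out_dir, sprintf("%s_%s_coverage.bedGraph", ds$name, cond))
      write_signal_track(ds[[cond]]$track, cb); add(cb)
    }
    ds_cfg[[length(ds_cfg) + 1]] <- list(
      name = ds$name, marker = ds$marker,
      control = list(peaks = sprintf("%s_control_peaks.bed", ds$name),
                     signal = sprintf("%s_control_coverage.bedGraph", ds$name)),
      treated = list(peaks = sprintf("%s_treated_peaks.bed", ds$name),
                     signal = sprintf("%s_treated_coverage.bedGraph", ds$name)))
  }
  dg <- file.path(out_dir, "deg.tsv")
  utils::write.table(
    data.frame(gene = study$deg_table$gene_id,
               log2fc = study$deg_table$log2fc,
               pvalue = study$deg_table$pvalue),
    dg, sep = "\t", quote = FALSE, row.names = FALSE)
  add(dg)
  dl <- file.path(out_dir, "disease_genes.txt")
  writeLines(c("# disease DEG gene list", study$disease_genes), dl); add(dl)
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(study$truth, tj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  add(tj)
  cfg <- list(datasets = ds_cfg,
              stitch_distance = study$params$stitch_distance,
              bin_width = study$params$bin_width,
              min_overlap_frac = 0,
              tss_exclusion = list(enabled = FALSE, window = 2500),
              deg = list(table = "deg.tsv", lfc_min = 1, q_max = 0.05),
              disease_genes = "disease_genes.txt",
              gene_model = "genes.tsv",
              venn_mode = "interval",
              output_dir = "results",
              seed = study$params$seed)
  cy <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cy); add(cy)

  files <- unlist(files)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
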