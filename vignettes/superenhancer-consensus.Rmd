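---
title: "Super-enhancer calling, differential dynamics and consensus target nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-enhancer calling, differential dynamics and consensus target nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seconsensus)
```

## The problem

Super-enhancers (SEs) are clusters of enhancers that concentrate
exceptionally high levels of activating chromatin marks (H3K27ac) or
coactivator occupancy (BRD4, MED1) and drive cell-identity genes. In a
differentiation experiment — for example mesenchymal stem cells before and
after osteogenic induction — the SEs gained by the induced condition point
at the regulators of the new cell state. Because SE calls vary between cell
lines and between markers, a robust nomination strategy intersects the
condition-gained SEs across several independent datasets and then requires
the consensus target genes to also be differentially expressed, both in the
experiment at hand and in a disease cohort. This package implements that
whole chain as composable, tested functions plus a config-driven runner.

## The SE model

**Stitching.** Enhancer peaks on a chromosome are merged whenever the gap
between consecutive peaks is at most the stitch distance $d$ (default
12 500 bp, the conventional choice). The rule is boundary-inclusive: a gap
of exactly $d$ merges. Stitching partitions the peak set — every peak ends
up in exactly one stitched region — and is idempotent.

**Scoring.** Each stitched region is scored by its integrated coverage,
$\sum_b v_b \cdot w_b$, the bin value times the overlapped width in bp,
over all bins intersecting the region. An optional control track is
subtracted before clamping at zero; subtraction is off by default because
the standard procedure ranks raw (RPKM-normalized) signal.

**The slope-1 cutoff.** With the $n$ region scores sorted ascending and
scaled to the unit square,

$$x_i = \frac{i}{n-1}, \qquad y_i = \frac{s_i}{\max_j s_j}, \qquad i = 0, \dots, n-1,$$

the cutoff sits at $\arg\min_i (y_i - x_i)$ — the point where a line of
slope 1 supports the convex rank–signal ("hockey-stick") curve from below.
Regions with signal *strictly greater* than the cutoff value are SEs; the
tangent-point region itself is a typical enhancer (TE), matching the usual
"signals higher than" reading. The SE set is therefore always a top-$k$
suffix of the ranking, and membership is invariant to positive scaling of
the track.

Degenerate curves are resolved conservatively: argmin ties go to the
largest index, so an exactly linear curve ($y_i = x_i$) and a flat curve
both yield zero SEs, and an all-zero score vector returns cutoff 0 with no
SEs. Negative scores (possible only after control subtraction) are clamped
to zero before the cutoff search. Score ties are ordered by (chrom, start)
so ranking is deterministic.

```{r}
fit <- find_se_cutoff(c(0, 1, 2, 4, 8, 16, 32, 64))
fit$cutoff_value          # 16: two regions exceed it
```

## Coordinates and signal representation

All coordinates are 0-based half-open (BED native); 1-based formats
(GTF-lite gene lines, bigWig via rtracklayer) are converted at the I/O
boundary, never downstream. Chromosome names are taken verbatim, with an
opt-in `harmonize_chr` flag, because silently rewriting names hides
dataset-mixing errors.

Coverage lives in fixed-width bins per chromosome. bedGraph records are
binned with *length-weighted averaging*: a record partially covering a bin
contributes in proportion to the covered width, so the integrated mass
$\sum_b v_b w$ equals $\sum_r v_r (e_r - s_r)$ to floating tolerance. The
implementation evaluates the cumulative integral of the step function at
bin edges, which is exact and vectorized; a tiny negative residue
($< 10^{-9}$ relative) that floating cancellation can leave on empty bins
is clamped to zero. RPKM normalization is the closed form
$c \cdot 10^9 / (w \cdot N)$ per bin ($w$ = bin width in bp, $N$ = library
size in reads), computed in exactly that association so integer inputs
reproduce it bit-for-bit; double normalization is refused.

Regions on chromosomes absent from a track read as zero with a warning
rather than an error — multi-dataset studies routinely mix tracks with
different chromosome complements, and a hard failure would make the
consensus analysis impractical. Positions beyond the end of a chromosome
also read as zero, which keeps profile-matrix rows a constant length.

## Profile matrices

`profile_matrix()` reproduces the usual computeMatrix semantics:
*reference-point* mode samples $[\mathrm{center} - f, \mathrm{center} + f)$
into `n_bins` equal bins, with the center defined as
$\lfloor (start + end)/2 \rfloor$; *scale-regions* mode rescales the region
body to `n_bins` bins with `n_flank_bins` fixed-width flank bins on each
side. The flank bin count is a separate parameter (default
$\lceil n_{bins}/2 \rceil$) because rows must have equal length while
region bodies vary; it is presentation configuration, not a scientific
claim, as are the defaults of 5 000 bp flank and 50 bins. Minus-strand rows
are reversed so "upstream" is always left.

## Differential SE dynamics and consensus

The comparison between conditions is strictly presence/absence, not a
count-based test. A treated SE is **shared** when some control SE overlaps
it by at least $\max(1\,\mathrm{bp},\, f \cdot \min(w_1, w_2))$ — $f$ is
`min_overlap_frac`, default 0, i.e. any 1-bp overlap counts, the most
permissive reading and the one we default to because the field rarely
states its overlap criterion; anything stricter is opt-in. Treated SEs with
no partner are **gain**, control SEs with no partner are **lost**, and
swapping the inputs swaps gain and lost exactly.

The cross-dataset consensus anchors on the first dataset's gain set: a
region is in the consensus iff every other dataset has a gain SE
overlapping it under the same rule, and the reported interval is the
intersection span of the matched representatives (clamped to the anchor
when representatives only overlap the anchor at opposite ends, which cannot
happen for the clustered gains the analysis targets). On such clustered
data the definition is symmetric and the result is invariant to dataset
order, which the tests check. Because the consensus is defined by overlap
with all datasets, adding a dataset can only shrink it.

Regions are annotated to the gene with the nearest strand-aware TSS
($start$ on +, $end - 1$ on −) from the region center, ties to the smaller
TSS coordinate then lexicographic gene id. Nearest-TSS search is restricted
to the region's own chromosome — cross-chromosome "distance" is undefined —
and a region on a chromosome with no annotated gene gets `NA` with a
warning rather than a fabricated assignment. The reported distance is 0
when the center falls inside the assigned gene body. The pipeline offers
the cross-dataset intersection both at the interval level (default) and at
the gene level (`venn_mode: gene`), since a consensus reported "by locus"
admits both readings.

## DEG integration

DEG tables are consumed, not produced: the differential-expression model
itself (DESeq2 and kin) is out of scope. Filtering applies the conventional
cutoffs inclusively — $|\log_2 fc| \ge 1$ and $Q \le 0.05$ by default,
boundary values in. Tables carrying only p-values are completed by
Benjamini–Hochberg adjustment (`bh_adjust()`, a validated wrapper over
`stats::p.adjust`); parsing never imputes silently. Candidate nomination is
the plain triple intersection of consensus-SE genes, upregulated DEGs and
the disease gene list. Identifier matching is exact and case-sensitive;
near-misses that would match after upper-casing are warned about, and
`harmonize_case = TRUE` opts into harmonization — useful when a disease
list uses mouse-style capitalization. No direction is imposed on the
disease list by default because published disease DEG lists often mix
directions; a caller wanting "down in disease" can pass the filtered subset.

## The synthetic study generator

`simulate_study()` builds the multi-dataset, two-condition structure the
pipeline is designed for, with known truth: a slot grid keeps every planted
feature more than one stitch distance from its neighbours; each planted SE
is `constituents_per_se` boxcar peaks (1 200 bp, 1 800 bp gaps by default)
centred on its target gene's TSS; background singleton enhancers of varying
length play the TE population; coverage is the sum of boxcar bumps
(amplitude 20 for SE constituents, 2 for background) plus zero-truncated
Gaussian noise (sd 1); and the DEG table upregulates gain-SE targets
($\log_2 fc \sim N(3, 0.5)$, p-values $\le 10^{-8}$) against null genes
($N(0, 0.3)$, uniform p). The disease list holds the shared-gain targets
plus 30 decoy genes. Boxcars aligned to bin boundaries were chosen over
Gaussian bumps because their integrals have an exact closed form, which
makes oracle tests exact; truncation at zero respects the non-negativity of
raw coverage. The default genome is 2 chromosomes × 10 Mb with 200 genes,
5 datasets (the typical cell-line × marker design), 1 shared-gain SE,
3 private-gain, 3 lost and 5 constitutive SEs per dataset, and 200
background peaks — sizes chosen so a full study simulates and analyses in
seconds on a laptop while still exercising every pipeline stage; the test
suite uses these defaults for end-to-end checks and a 1 × 3 Mb / 2-dataset
variant for unit tests.

What the generator deliberately does **not** emulate: read-level sampling
noise (coverage is a smooth field, not piled reads), correlated chromatin
domains, assembly mixing, peak-caller artifacts, or partially overlapping
SE boundaries between conditions. Passing tests therefore demonstrate the
correctness of the interval algebra, scoring, cutoff and set logic — not
robustness to alignment or peak-calling pathologies, which are upstream of
this package's inputs.

## The pipeline runner

`run_pipeline()` consumes a YAML config (one entry per dataset with
control/treated peaks and coverage), runs call → classify → consensus →
annotate → filter → intersect, and writes per-dataset SE tables and BEDs,
gain/lost/shared BEDs, `consensus.tsv`, `candidates.tsv`, a structured
`run.log`, and `report.json` containing every parameter, every count, and
input checksums. Counts are reported three ways — per dataset, raw union,
and overlap-deduplicated union — because aggregate "total gain SE" numbers
are ambiguous without stating the rule. The last pipeline step is a
self-consistency audit that re-reads the emitted files and fails the run if
any report count disagrees. The pipeline itself is deterministic; the only
seeded component in the package is the simulator. A failed stage leaves a
`FAILED` status and the error message in `report.json`.

```{r, eval = FALSE}
study <- simulate_study(se_sim_params(seed = 42))
dir <- tempfile("study")
write_study(study, dir)
report <- run_pipeline(file.path(dir, "config.yaml"))
report$candidates            # the planted shared-gain target gene
```

## Known limitations

* Presence/absence dynamics cannot distinguish an SE that shrank below the
  cutoff from one that vanished; quantitative differential SE testing is
  intentionally out of scope.
* The consensus is anchored on the first dataset; for pathological overlap
  topologies (chains of half-overlapping regions) the anchored and fully
  symmetric definitions can differ.
* Nearest-TSS annotation is a heuristic; 3D-contact-based target assignment
  is out of scope.
* Genome assemblies are the user's responsibility: no lift-over is
  performed, and chromosome names are matched verbatim unless harmonization
  is requested.
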