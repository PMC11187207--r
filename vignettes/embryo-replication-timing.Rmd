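---
title: "Single-cell replication timing and copy-number fragility in early embryos"
author: "scEmbryoRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell replication timing and copy-number fragility in early embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scEmbryoRT)
```

## The measurement model

A single blastomere sequenced at shallow depth yields binned read counts
whose expectation tracks local DNA copy number. Two biological signals live
in that copy number:

* **Replication timing (RT).** During S-phase, a genomic bin that has
  already replicated carries twice the DNA of one that has not. Across a
  population of S-phase cells sampled at different points of S-phase, the
  fraction of cells in which a bin is "2x" estimates how early the bin
  replicates.
* **Chromosomal aneuploidy and breakage.** Whole-chromosome and segmental
  copy-number changes acquired after fertilization appear as persistent
  level shifts; the boundary of a segmental change marks a chromosome
  break site.

The package implements the full desk-side analysis: per-cell QC and
normalization to a G1 reference, binarization of S-phase cells into
replicated/unreplicated bins, aggregation to a replication-percentage
profile with early (> 50% of cells replicated) and late (< 50%) classes,
copy-number segmentation with break sites annotated at transitions with
|ΔCN| > 1, enrichment of sites against length-matched random regions
(gene/origin density, lamina-association observed/expected, A/B compartment
sign, Mann-Whitney and one-way ANOVA tests), and DNA-fiber arithmetic
(2.59 kb/μm, fork speed = track/pulse, inter-origin distances).

## What the generator emulates

`makeRTTruth()` draws a smooth per-bin replication schedule `t ∈ [0, 1]`
(a Gaussian field smoothed over `correlationLengthBins` bins — default 20,
i.e. 2 Mb at 100 kb bins, the scale of replication-timing domains — mapped
through its empirical CDF) and couples feature tracks to it with strength
κ: lamina-associated domains with probability `plogis(4κ(t − 0.5))`
(the gain of 4 makes κ ≈ 1–3 span realistic LAD/RT contrasts while κ = 0
is exact independence), an A/B-compartment-like score `−tanh(κ(t − 0.5))`
plus smooth noise, origins and genes as Poisson processes with intensity
`∝ exp(−κt)`, and a GC fraction mildly decreasing in `t` (mean 0.42,
SD 0.03, the range seen in 100 kb mammalian bins).

`simulateCells()` reads the program out per cell. An S cell draws its
S-phase fraction `f ~ Uniform(0.1, 0.9)` — cells spanning most of S-phase,
before any QC filtering — and a bin is truly replicated when `t ≤ f`, with
independent flips at `flipRate` (default 0.02) standing in for
cell-to-cell replication heterogeneity. Expected counts are
`(1 + state) × exp(N(0, ampNoiseSd)) × exp(gcCoeff·(gc − mean gc))`,
rescaled to `meanReadsPerCell` (default 10^6) per cell; counts are negative
binomial with `var = μ + μ²/dispersion` (default dispersion 10, i.e. a
~32% coefficient of variation floor typical of whole-genome-amplified
single cells; `Inf` recovers Poisson). GC bias defaults to 0 — it is
opt-in, because the QC stage removes shared GC structure anyway (below).
`injectCNEvent()` multiplies counts in a region by
`(baseline + ΔCN)/baseline` with stochastic rounding.

The generator does **not** emulate several properties of real scWGA data:
mappability structure and shared per-bin amplification bias (only the mask
and the reference normalization address these), chimeric reads, fork-level
spatial structure, or allele-specific signal. Passing tests therefore show
that the inference machinery is correct under a faithful noise model, not
that the defaults match any particular protocol's bias spectrum.

## QC and phase calling

Copy ratios are `(c_b/Σc) / (r_b/Σr)` against a G1 reference. `qcCells()`
bootstraps the reference from the data: a first pass against a uniform
reference scores every cell's MAD (median absolute deviation of copy
ratios from their median, no consistency factor), and the quietest decile —
the most G1-like cells — forms the reference; an ensemble-mean reference
would be dominated by S cells and compress the very contrast the MAD
measures.

Per-cell GC-loess correction (`gcCorrect()`) is available but off by
default in `qcCells()`. GC content correlates with replication timing, so
a trend fitted on an S cell's own ratios absorbs part of the replication
signal; shared GC/amplification structure is already divided out by the
G1 reference, which is also why non-replicating cells are the right place
to estimate such trends.

Phase calling uses the conventional MAD thresholds (G1 < 0.3; S in
[0.4, 0.8]; the gray zone and everything above 0.8 excluded) as stored
defaults. On synthetic data the MAD scale depends on the simulated depth
and dispersion, so `calibratePhaseThresholds()` fits the cutpoint instead:
supervised (optimal single cutpoint against known labels) when truth is
available, otherwise by locating the tight low mode of the MAD
distribution and cutting three robust SDs above it. Cells at the extremes
of S-phase are genuinely G1-like in this statistic; no single MAD cutoff
separates them, which is the same reason the original thresholds exclude
low-MAD cells from RT analysis.

## Binarization

`binarizeCell()` denoises the per-cell ratio profile with a running median
(default 9 bins ≈ 0.9 Mb, well below the 2 Mb timing-domain scale) and
partitions the values by a deterministic two-means (centres initialized at
the 25th/75th percentiles; threshold = midpoint of centres). The median
filter is what makes per-bin accuracy ≥ 95% reachable at the default noise
level: with a 32% CV the raw two-level separation is only ~3 noise SDs,
and median filtering buys back a factor ~3 while passing clean level
steps through unchanged, so the noise-free case stays exact. Cells whose
centre separation falls below `minSep = 0.3` ratio units — very early or
very late S cells, or non-replicating cells that slip through QC — carry
too little copy contrast to binarize and are dropped from aggregation
rather than forced to 0%/100%.

Aggregation is a per-bin fraction over non-missing states; a bin masked in
a cell contributes to neither numerator nor denominator. The tie at
exactly 50% forms a third, boundary class because both the early and the
late definition are strict inequalities.

## Segmentation and the break rule

`segmentCell()` re-specifies shallow-WGS segmentation as penalized
least squares: per chromosome, recursive splitting accepts a boundary
when the SSE reduction exceeds `penalty × log(n) × σ̂²` per changepoint,
with σ̂² a robust first-difference estimate. Two design points matter:

* **Interior events need a pair search.** The best *single* split gain for
  a w-bin interior event on an n-bin chromosome scales as `w²/n·Δ²` and
  falls below any useful penalty; each recursion step therefore also
  scans the best pair of boundaries flanking an interior segment — the
  circular-binary-segmentation move used by the standard CNV stacks.
* **Boundaries are searched on log2 ratios** (`transform = "log2"`),
  because ratio noise scales with copy level; a local boundary polish
  then re-places each boundary against trimmed means of its flanking
  segments. The penalty default of 4 was set so that flat regions of the
  length handled here (hundreds of bins) essentially never split on
  noise; event gains at the scales of interest are two orders of
  magnitude above the threshold.

`callCopyNumber()` scales mean ratios so the length-weighted median equals
the baseline (2). Note the identifiability limit: if half the genome is
altered (e.g. a whole-chromosome loss on a two-chromosome genome), the
median anchor is ambiguous — calling requires a euploid majority or an
external reference. `annotateBreakpoints()` then applies the strict
|ΔCN| > 1 rule on *continuous* copy number: rounding first would hide a
change of 1.4, and the strict inequality means a clean ΔCN = 1 transition
never annotates. Break positions are reported as the 0-based coordinate of
the left edge of the right segment's first bin. In the pipeline, copy
number is read out on non-replicating cells only, since S-phase
bimodality masquerades as segmental change.

## Enrichment statistics

Random regions are length-matched per query site and sampled uniformly
over unmasked stretches (weighted by the number of admissible start
positions, so placement is exactly uniform over the admissible space).
The lamina observed/expected ratio compares the fraction of sites with any
LAD overlap against the LAD coverage of the unmasked genome; for point-like
sites (break-site coordinates) a uniform null gives OE = 1 by construction,
which the calibration check verifies by Monte Carlo. For extended sites the
any-overlap probability exceeds coverage — OE is then an enrichment
statistic relative to the analytic point expectation, and the Monte-Carlo
null (`sampleRandomRegions` + `laminaOE` per set) is the fair comparison.

`mannWhitney()` reports U for the first group from midranks. With both
groups of size ≤ 8 the p-value enumerates all group assignments and counts
those whose U deviates from the null mean at least as much as observed —
enumeration is correct under ties, which is why the exact branch has no
tie guard. Larger samples use the normal approximation with tie correction
and a 0.5 continuity correction. One-way ANOVA delegates to the classical
equal-variance F test.

## Fiber arithmetic

Track lengths in μm convert at 2.59 kb/μm; fork speed divides by the pulse
duration (default 30 min); inter-origin distances are adjacent differences
of sorted origin midpoints, pooled across fibers, with fibers carrying
fewer than two origins contributing nothing. Group summaries report
medians over pooled tracks (per-embryo aggregation is a deliberate
non-default: pooling is what the group sizes in typical fiber experiments
support).

## Numerical and degenerate-input conventions

* Coordinates are held in `GRanges` (1-based, closed) and converted
  to/from the BED 0-based half-open convention at every reader/writer.
* Interval-to-bin counting assigns by interval midpoint, so a gene
  spanning a bin edge is counted exactly once.
* The last, short bin of a chromosome is masked by default (unequal
  exposure); masked bins propagate as `NA` and drop from all denominators.
* Division by a zero-count reference bin masks the bin for that cell;
  an all-zero cell, an all-masked genome, zero expected LAD coverage and
  zero-variance correlation inputs raise descriptive errors rather than
  returning NaN.
* Writers emit sorted, tab-separated text with numbers at 10 significant
  digits; identical configurations reproduce byte-identical outputs.

## Problem sizes used in the checks

The bundled checks run on a two-chromosome, 2 × 100 Mb genome at 100 kb
bins (2,000 bins), with 30 G1 + 150 S cells at one million reads each for
RT recovery, 50 single-event cells for break recall, 100 random 60-bin
chromosomes for the segmentation oracle, 1,000 random site sets for OE
calibration and 10,000 null draws for the rank-test calibration — sizes at
which every property is measured with comfortable Monte-Carlo margin on a
single CPU.

## Known limitations

* MAD-based phase calling cannot separate S cells at the extreme ends of
  S-phase from G1 cells; they are excluded by design, not recovered.
* Copy-number scaling assumes a euploid majority per cell.
* Boundary localization of copy-number gains is noise-limited: at the
  default depth and dispersion, a known-true-means estimator makes the
  same ±2-bin errors the package makes, so sub-bin accuracy claims are
  not meaningful at this coverage.
* The Mann-Whitney normal approximation is used above group size 8;
  p-values in the far tail (< 1e-10) are approximation-limited.

## A short tour

```{r tour, eval = FALSE}
bins <- partitionGenome(c(chr1 = 1e8, chr2 = 1e8), binSize = 1e5)
truth <- makeRTTruth(bins, seed = 7)
cells <- simulateCells(truth, seed = 7)

qc <- qcCells(cells, thresholds = "calibrate")
sCells <- qc$qc$cell[qc$qc$phase == "S"]
binary <- binarizeCells(qc$copyRatio[, sCells], bins = genomeBins(cells))
profile <- aggregateProfile(binary, genomeBins(cells))
table(rtClass(profile))

seg <- callCopyNumber(segmentCell(qc$copyRatio[, 1], genomeBins(cells),
                                  cellId = qc$qc$cell[1]))
annotateBreakpoints(seg)
```

Or end to end, with every table written to disk:

```{r pipeline, eval = FALSE}
res <- runPipeline(defaultPipelineConfig(seed = 7), outDir = "rt-demo")
```
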