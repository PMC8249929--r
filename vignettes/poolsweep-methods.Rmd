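---
title: "Pool-Seq selective-sweep scans with poolsweep"
author: "poolsweep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-Seq selective-sweep scans with poolsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
library(GenomicRanges)
```

## The problem and the data

Pooled whole-genome resequencing (Pool-Seq) sequences one library made
from the DNA of many individuals; the frequency of an allele in the pool
is estimated by its share of the read depth at the site. The design this
package targets is a three-pool contrast: one pool with the ancestral
phenotype (here called *gray*) and two independent pools with the derived
phenotype (*white1*, *white2*). A selective sweep that drove a derived
allele to high frequency in the white pools leaves two footprints:

* **heterozygosity deficit** in the swept pools — measured by pooled
  heterozygosity Hp and its negated Z-score −ZHp; and
* **allele-frequency differentiation** between gray and white —
  measured by the Weir–Cockerham F~ST~ estimator.

Requiring both signals in both white pools, via top-quantile thresholds
and intersections, suppresses drift and artefact signals that would pass
a single scan.

The atom of all computation is a `PoolCounts` object: a `GRanges` of
1-based SNP positions plus an integer array of read counts with
dimensions sites × alleles (A, T, C, G, N, del — the sync column order) ×
pools. Counts arrive either from a PoPoolation2 sync file (`readSync`)
or from per-sample allele-depth fields of a VCF (`readAlleleDepthVcf`).
"N" and "del" counts never enter depth or frequency computations;
deletions are handled by the indel-proximity site filter instead.

## Site filtering

`filterSites` retains a SNP iff

* every pool's nucleotide read depth lies in `[minDepth, maxDepth]`
  (defaults 10 and 100) — depth below 10 makes read-based frequencies
  unusable, depth above 100 flags collapsed repeats;
* the site quality, when supplied, is ≥ `minQuality` (default 20,
  phred-scaled); with no qualities the check is skipped and the skipped
  count reported;
* the minor allele frequency is ≥ `minMAF` (default 0.05); and
* no indel lies within `indelExclusionBp` (default 15 bp, boundary
  inclusive), where alignment artefacts concentrate.

Rejections are attributed to the first failing check in the order depth,
quality, MAF, indel, and tallied for QC reporting.

One design choice deserves emphasis: **MAF is computed on counts summed
over all pools**, not per pool. A site fixed in the white pools but
segregating in gray is exactly the signature the scan is looking for; a
per-pool MAF rule would discard those sites and erase the Hp signal. The
pooled rule corresponds to the site's "SNP" status in joint variant
calling across the pools. Per-pool depth bounds, by contrast, mirror the
min/max coverage semantics of standard Pool-Seq window tools, which
require coverage in every pool.

## Window statistics

Windows are a fixed tiling anchored at scaffold position 1:
`[1, w], [w+1, 2w], …` with `w = 10000` by default; a site at position
*p* belongs to window `ceiling(p / w)`, so position 10000 falls in
window 1 and 10001 in window 2. Windows with fewer than `minSnps = 10`
SNPs are discarded before any distribution is formed — sparse windows
produce noisy Hp and F~ST~ values. A trailing partial window (known when
scaffold lengths are available) is clipped and kept if it still meets
the SNP minimum. The min-SNP filter is applied *before* the −ZHp moments
are computed, so the standardisation describes exactly the windows that
can be selected.

### Pooled heterozygosity

With per-SNP major/minor read counts n~MAJ~, n~MIN~ (ties for the major
allele broken by the fixed order A < C < G < T; Hp is symmetric in the
two counts, so the tie-break cannot change the value):

$$Hp = \frac{2 \sum n_{MAJ} \sum n_{MIN}}
           {\left(\sum n_{MAJ} + \sum n_{MIN}\right)^2}$$

Since $2xy/(x+y)^2 \le 1/2$ with equality at $x = y$, Hp ∈ [0, 0.5]. An
empty window is undefined (`NA`), never 0 — 0 is a strong sweep signal
and must not be manufactured by absence of data. Per pool,

$$-ZHp = -\frac{Hp - \mu_{Hp}}{\sigma_{Hp}}$$

with moments over that pool's retained windows. The standard deviation
uses the sample (n−1) denominator by default; with thousands of windows
the choice is numerically immaterial, but it is fixed (and switchable via
`sdType`) so results are exactly reproducible.

### Weir–Cockerham F~ST~

Read counts are not genotypes: a pool of N diploids sequenced to depth d
carries at most `min(d, 2N)` independent chromosomes. The estimator
therefore treats each site as two samples of allele indicators with
effective sizes $n_i = \min(d_i, \text{haploid pool size}_i)$ and
allele-1 frequencies $p_i$ from the read counts, and applies the
two-population Weir–Cockerham ANOVA form:

$$\mathrm{MSP} = \sum_i n_i (p_i - \bar p)^2, \qquad
  \mathrm{MSG} = \frac{\sum_i n_i p_i (1 - p_i)}{n_1 + n_2 - 2}, \qquad
  n_c = n_1 + n_2 - \frac{n_1^2 + n_2^2}{n_1 + n_2}$$

$$\hat\theta = \frac{\mathrm{MSP} - \mathrm{MSG}}
                    {\mathrm{MSP} + (n_c - 1)\,\mathrm{MSG}}$$

A window combines its sites as the ratio of summed numerators to summed
denominators — the standard multi-locus Weir–Cockerham combination.
Negative values (expected under no differentiation, where the estimator's
mean is slightly below zero) are reported as computed: truncating at zero
would distort the upper-tail quantile the scan thresholds on. At each
site the biallelic pair is the two most abundant nucleotides of the two
pools combined; sites covered in only one pool are excluded from F~ST~
but kept for that pool's Hp, which is a single-pool statistic.

The haploid pool sizes are required arguments (for the default three-pool
design: 234, 50 and 174 chromosomes from 117, 25 and 87 diploids).

## Thresholds and the three-step call

`topQuantileThreshold` computes the cutoff of the upper `topFraction`
(default 3%) tail as the empirical quantile at probability 1 − f under
the "higher" interpolation rule — the sorted value at index
`ceiling((n−1)(1−f) + 1)` — and selects every window at or above it, ties
included. For values 1…100 at f = 0.03 the cutoff is 98 and three
windows are selected. This rule is deterministic, conservative (it never
selects below the nominal tail), and its tie policy can only enlarge the
selection, which is the safe direction for a screening step. A
distribution with no tail (all values identical) is an error rather than
an arbitrary selection.

The call then proceeds:

1. `intersectScans` on the top windows of the two F~ST~ comparisons
   (gray vs white1, gray vs white2) — windows matched exactly by
   (scaffold, start, end); overlapping-but-unequal windows mean the scans
   were run on different tilings and raise an error.
2. The same for the top −ZHp windows of the two white pools.
3. `finalOverlap` intersects (1) and (2); maximal runs of adjacent
   surviving windows are merged into *regions* for reporting, while the
   window list (with every contributing statistic) is retained.

"Region" is defined here as a maximal run of adjacent surviving windows.
This is an assumption of the reporting layer, recorded as such: region
*counts* depend on it, window-level results do not.

`overlapGenes` reports a gene when a final region intersects the gene
span extended by `flankBp = 10000` on each side (clipped at position 1,
boundaries inclusive) — regulatory changes near a gene are standard sweep
candidates, so gene "coverage" includes 10-kb flanks. Overlap with flank
0 is always a subset of overlap with a positive flank.

## The synthetic-data generator

`simulatePoolCounts` emulates the statistical structure the scan assumes,
not a population-genetic history (no coalescent, recombination or
demography — by design; see Limitations):

* SNP positions: binomial thinning of each scaffold at `snpDensity`
  (default 0.002/bp, ≈ 20 SNPs per 10-kb window, so the min-10-SNP
  filter occasionally bites without dominating).
* Baseline derived-allele frequency per site: uniform on
  `mafRange = [0.05, 0.5]`, shared across pools, so sites pass the MAF
  filter by construction; a contamination below 0.05 can be injected by
  widening the range to exercise the filter.
* Pool-specific drift: Gaussian noise, sd `driftSd = 0.02`, on the
  shared frequency — enough to make pools distinguishable without
  generating sweep-like outliers.
* Planted sweeps: inside each configured region, the target pools'
  derived frequency is set to `derived_freq` (the white pools at 0.98 in
  the standard scenario), reducing expected Hp there and raising
  expected F~ST~ against non-target pools.
* Reads: depth per pool/site is Poisson around `mean_depth` (default 44,
  the effective depth of the emulated study design), truncated to
  [1, 3·mean] so the depth filter's rejection paths are exercised; reads
  are binomial in the pool's true frequency; each read is miscalled to a
  uniformly chosen other nucleotide with probability
  `errorRate = 0.001`.
* Determinism: the same `seed` yields a byte-identical dataset.

The generator returns the truth set (per-site true frequencies per pool
and the planted regions), and `writeSimulation` emits sync + truth TSV +
sweeps BED. `simulateGenotypeTable` draws genotype-count tables
(multinomial per group) to exercise the association statistics, including
their null behaviour.

What passing tests on this generator do **not** show: robustness to
linkage structure, background selection, depth heterogeneity along the
genome, mapping bias, or indel-rich regions. The generator targets the
assumptions of the statistics; performance on real data also depends on
upstream alignment and calling quality.

## Validation statistics

* `chiSquareAssociation`: Pearson χ² without continuity correction,
  after pruning genotype rows (and group columns) whose counts are all
  zero — an unobserved genotype class contributes no information but
  breaks expected counts. Small expected cells (< 5) are counted and
  reported, not fatal: validation tables of nearly-fixed loci contain
  them unavoidably, and the statistic is used as a ranking/screening
  quantity.
* `fisherAlleleDepth`: exact two-sided hypergeometric p on the 2×2
  major/minor read-count table of one SNP in two pools, used to rank
  SNPs for validation; a zero margin gives p = 1 with a warning.
* `afFromGenotypes`: allele frequency `(2·hom + het) / (2N)` from a
  genotype-count column.
* `kendallW`: concordance of m rankings of n items with mid-ranks and
  the tie-corrected denominator `m²(n³−n) − mT`; with m = 2, identical
  orderings give W = 1 and reversed orderings W = 0. Significance uses
  the χ² approximation m(n−1)W on n−1 df. The typical use is comparing
  pooled-read and genotype-based allele-frequency estimates of the same
  loci.
* `lofCategorize`: maps Sequence Ontology consequence terms to the four
  loss-of-function categories (1 stop gain/loss, 2 frameshift,
  3 essential splice site, 4 initiator codon); everything else is `NA`.

## Numerical and interface choices

* Coordinates are 1-based inclusive internally (sync/GFF3 convention);
  BED is converted at the boundary (`start_bed = start − 1`), and the
  conversion round-trips exactly.
* Pool identity in sync files is positional; names are supplied by the
  caller or default to `pool1…poolK`.
* Degenerate inputs fail loudly rather than silently: all-zero count
  sites, empty Hp windows, zero-variance −ZHp scans, identical-value
  threshold distributions, sub-2×2 pruned genotype tables, constant
  Kendall columns.
* Multiallelic VCF records are split into one biallelic record per ALT
  (sharing the REF depth) and flagged; records lacking the depth field
  are skipped and counted.
* `runSweepPipeline` writes every output with fixed 6-decimal formatting
  and an md5 manifest, so identical configuration and inputs give
  byte-identical results. The stage functions (`filterSites`, `hpScan` /
  `zhpScan`, `fstScan`, `selectTopWindows`, `intersectScans`,
  `finalOverlap`, `overlapGenes`, the readers/writers) are the
  "subcommands": each stage is independently invocable and tested, and a
  thin command-line wrapper (`inst/scripts/run_poolsweep.R`) drives the
  whole pipeline from a shell.

## Problem sizes used in the test suite

The packaged checks run the full scan on synthetic genomes of 1–5
scaffolds × 0.2–1 Mb at SNP density 0.002 with the default three-pool
design, and repeat the planted-sweep scenario over 20 seeds; oracle
comparisons use 1000-site fixtures. These sizes give stable statistics
(hundreds to thousands of retained windows) while keeping a full suite
run in the order of a minute. The same machinery scales to genome-sized
inputs linearly in the number of sites.

## Known limitations

* The F~ST~ implementation is the allele-frequency (haploid ANOVA) form
  of Weir–Cockerham with depth-capped sample sizes. Tools that model
  pool noise hierarchically, or PoPoolation2's own discretised
  implementation, will produce slightly different per-window values;
  rankings and top-quantile sets are expected to agree closely, exact
  numbers are not.
* Hp treats read counts as if they were allele draws; at low depth the
  binomial sampling noise inflates apparent heterozygosity variance.
  The min-SNP and depth filters bound, but do not remove, this effect.
* Region counts depend on the adjacent-window merge convention.
* The scan statistics are window summaries; sub-window localisation of
  the selected site is out of scope, as are alignment, variant calling,
  consequence prediction and enrichment analysis, which belong to
  upstream/downstream tools.
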