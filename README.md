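# poolsweep

Selective-sweep detection from pooled whole-genome resequencing
(Pool-Seq) data.

In a Pool-Seq experiment, DNA from many individuals of a population is
sequenced as a single library, and allele frequencies are estimated from
per-allele read depths instead of individual genotypes. When an allele has
been driven to high frequency by (artificial) selection — for example
during domestication — the surrounding region shows a deficit of
heterozygosity in the selected population and elevated allele-frequency
differentiation against an unselected one. `poolsweep` implements the
genome scan that exploits both signals, for the classic design of one
reference pool ("gray") contrasted with two selected pools ("white"), and
the validation statistics used to check Pool-Seq allele frequencies
against individual genotyping.

## The statistics

For each pool and SNP, let `n_MAJ` and `n_MIN` be the read counts of the
most and least abundant allele. In non-overlapping 10-kb windows, the
pooled heterozygosity is

    Hp = 2 * (sum n_MAJ) * (sum n_MIN) / (sum n_MAJ + sum n_MIN)^2

which lies in [0, 0.5] and drops toward 0 inside a sweep. Per pool,
window values are standardised and negated,

    -ZHp = -(Hp - mean(Hp)) / sd(Hp)

so sweeps appear as large positive scores. Between-pool differentiation
is measured by the two-population Weir–Cockerham F_ST estimator computed
from read-count allele frequencies (effective allele sample size per pool
= min(read depth, haploid pool size)), combined over the SNPs of a window
as a ratio of summed variance components.

Candidate sweeps are called in three steps: (1) windows in the top 3% of
the F_ST distributions of *both* gray-vs-white comparisons; (2) windows
in the top 3% of the −ZHp distributions of *both* white pools; (3) the
intersection of (1) and (2). Windows with fewer than 10 SNPs are
discarded first; adjacent surviving windows are merged into regions, and
genes within 10 kb of a region are reported.

The companion validation toolkit covers Pearson χ² genotype–phenotype
association on genotype-count tables, Fisher's exact test on allele read
depths, allele frequencies from genotype counts, Kendall's coefficient of
concordance W between pooled-read and genotype-based allele-frequency
estimates, and loss-of-function consequence categorisation.

A synthetic-data generator (`simulatePoolCounts`) emulates the three-pool
design — 117, 25 and 87 diploids at ~44× depth — with planted sweep
regions and a known truth set, so the whole pipeline is testable without
any external data.

## Worked example

Simulate two 1-Mb scaffolds with a 50-kb sweep planted at
scaffold01:200001–250000 in both white pools, then run the three-step
scan:

```r
library(poolsweep)

sw  <- data.frame(scaffold = "scaffold01", start = 200001L, end = 250000L,
                  target_pools = "white1,white2", derived_freq = 0.98)
cfg <- SimulationConfig(nScaffolds = 2, scaffoldLength = 1e6,
                        sweepRegions = sw, seed = 42)
sim <- simulatePoolCounts(cfg)
flt <- filterSites(sim$counts)      # depth 10-100, MAF >= 0.05

z1 <- zhpScan(flt$counts, "white1");  z2 <- zhpScan(flt$counts, "white2")
f1 <- fstScan(flt$counts, "gray", "white1", c(234, 50))
f2 <- fstScan(flt$counts, "gray", "white2", c(234, 174))

fi <- SweepCallSet("FST_INTERSECT", intersectScans(
        selectTopWindows(f1, "Fst")$windows,
        selectTopWindows(f2, "Fst")$windows))
zi <- SweepCallSet("ZHP_INTERSECT", intersectScans(
        selectTopWindows(z1, "negZHp")$windows,
        selectTopWindows(z2, "negZHp")$windows))
finalOverlap(fi, zi)
#> SweepCallSet [FINAL_OVERLAP]: 5 windows in 1 regions
```

The five surviving 10-kb windows merge into exactly the planted region,
scaffold01:200001–250000. A gene 5 kb beyond the region's edge is still
reported because overlap includes 10-kb flanks:

```r
genes <- GenomicRanges::GRanges("scaffold01",
           IRanges::IRanges(255000, 260000), gene_id = "exampleGene")
overlapGenes(finalOverlap(fi, zi), genes)[, 1:6]
#>       gene_id   scaffold gene_start gene_end n_regions                  regions
#> 1 exampleGene scaffold01     255000   260000         1 scaffold01:200001-250000
```

Validation-side example — a genotype table of one SNP (rows genotypes,
columns phenotype groups of 114/25/84 genotyped birds):

```r
kitlg <- rbind(GG = c(37, 22, 84), GA = c(77, 3, 0), AA = c(0, 0, 0))
chiSquareAssociation(kitlg)[1:3]
#> $statistic
#> [1] 102.8887
#> $df
#> [1] 2
#> $p.value
#> [1] 4.549922e-23
```

The all-zero `AA` row is pruned automatically; the statistic says the
genotype distribution differs strongly between the phenotype groups.

`runSweepPipeline()` wires all stages together from a flat `key = value`
configuration file and writes per-scan window tables, thresholds, final
regions (BED), gene hits and an md5 manifest;
`inst/scripts/run_poolsweep.R` is a thin command-line wrapper around it.

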