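Package: poolsweep
Title: Selective Sweep Detection from Pooled Sequencing Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-scan analysis for pooled whole-genome resequencing
    (Pool-Seq) experiments. Computes pooled heterozygosity (Hp) and its
    negated Z-transform (-ZHp) together with Weir-Cockerham F_ST in
    non-overlapping genomic windows from per-pool allele read counts,
    detects candidate selective sweeps as the intersection of the top
    quantiles of both scans across population comparisons, and overlaps
    the resulting regions with gene annotations including flanking
    sequence. Also provides the validation statistics used alongside such
    scans (genotype-table chi-square association, Fisher's exact test on
    allele read depths, allele frequencies from genotype counts, Kendall's
    coefficient of concordance, loss-of-function consequence
    categorisation) and a synthetic-data generator that plants sweeps with
    a known truth set so the whole pipeline is testable without external
    data. Reads and writes PoPoolation2 sync, VCF, GFF3, BED and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
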