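suppressPackageStartupMessages({
  library(GenomicRanges)
})

# Direct transcription of the pooled-heterozygosity formula, kept separate
# from the implementation path.
hp_direct <- function(nMaj, nMin) {
  2 * sum(nMaj) * sum(nMin) / (sum(nMaj) + sum(nMin))^2
}

# Weir-Cockerham two-population oracle via an explicit ANOVA on 0/1 allele
# indicator vectors fitted with stats::lm. a1/a2 are allele-1 counts out of
# n1/n2 sampled alleles in each pool. Returns the per-site mean squares and
# nc, so windows can be combined as a ratio of sums.
wc_anova_site <- function(a1, n1, a2, n2) {
  y <- c(rep(1, a1), rep(0, n1 - a1), rep(1, a2), rep(0, n2 - a2))
  g <- factor(rep(c("A", "B"), c(n1, n2)))
  av <- suppressWarnings(anova(stats::lm(y ~ g)))
  msb <- av["g", "Mean Sq"]
  msw <- av["Residuals", "Mean Sq"]
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  list(num = msb - msw, den = msb + (nc - 1) * msw)
}

wc_anova_window <- function(a1, n1, a2, n2) {
  comps <- Map(wc_anova_site, a1, n1, a2, n2)
  sum(vapply(comps, `[[`, numeric(1), "num")) /
    sum(vapply(comps, `[[`, numeric(1), "den"))
}

# Exhaustive two-sided Fisher p for a 2x2 table with fixed margins.
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kendall's W by the rank-sum formula, written independently of the
# implementation (no-ties algebraic form plus explicit tie correction).
kendall_w_direct <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  rk <- apply(mat, 2, rank)
  Ri <- rowSums(rk)
  S <- sum(Ri^2) - sum(Ri)^2 / n
  Tc <- 0
  for (j in seq_len(m)) {
    t <- table(rk[, j])
    Tc <- Tc + sum(t^3 - t)
  }
  12 * S / (m^2 * (n^3 - n) - m * Tc)
}

# Table of genotype counts printed for the four PCR-validated colour genes
# (rows: genotype classes; columns: Gray, White_1, White_2).
verified_genotype_tables <- function() {
  list(
    KITLG = rbind(GG = c(37, 22, 84), GA = c(77, 3, 0), AA = c(0, 0, 0)),
    MITF = rbind(GG = c(83, 6, 14), GC = c(29, 17, 49), CC = c(0, 2, 20)),
    TYRO3 = rbind(AA = c(31, 20, 86), AG = c(76, 5, 0), GG = c(0, 0, 0)),
    KIT = rbind(AA = c(0, 0, 0), AG = c(67, 2, 0), GG = c(35, 23, 78))
  )
}

.windowKeyTest <- function(gr) {
  paste(as.character(seqnames(gr)), start(gr), end(gr))
}

# Small PoolCounts builder for unit tests: counts is a list of per-pool
# sites x 4 matrices in A,C,G,T order.
make_pc <- function(scaffold, position, nucCounts, poolNames = NULL,
                    ref = NULL, seqlengths = NULL) {
  nPools <- length(nucCounts)
  n <- nrow(nucCounts[[1]])
  arr <- array(0L, c(n, 6, nPools),
    dimnames = list(NULL, syncAlleles(), poolNames)
  )
  for (k in seq_len(nPools)) {
    arr[, c("A", "C", "G", "T"), k] <- as.integer(nucCounts[[k]])
  }
  if (is.null(ref)) ref <- rep("A", n)
  PoolCounts(scaffold, position, ref, arr,
    poolNames = poolNames, seqlengths = seqlengths
  )
}

# Standard synthetic scenario with planted sweeps used by scan-level tests.
sweep_sim_config <- function(seed, nScaffolds = 5, scaffoldLength = 1e6,
                             sweeps = NULL) {
  if (is.null(sweeps)) {
    sweeps <- data.frame(
      scaffold = c("scaffold01", "scaffold02", "scaffold03"),
      start = c(200001L, 500001L, 800001L),
      end = c(250000L, 550000L, 850000L),
      target_pools = "white1,white2",
      derived_freq = 0.98
    )
  }
  SimulationConfig(
    nScaffolds = nScaffolds, scaffoldLength = scaffoldLength,
    sweepRegions = sweeps, seed = seed
  )
}

# Haploid pool sizes implied by the default three-pool design
# (117/25/87 diploids).
default_pool_sizes <- c(gray = 234, white1 = 50, white2 = 174)

run_three_step <- function(pc, poolSizes = default_pool_sizes,
                           topFraction = 0.03) {
  flt <- filterSites(pc)
  z1 <- zhpScan(flt$counts, "white1")
  z2 <- zhpScan(flt$counts, "white2")
  f1 <- fstScan(flt$counts, "gray", "white1", poolSizes[c("gray", "white1")])
  f2 <- fstScan(flt$counts, "gray", "white2", poolSizes[c("gray", "white2")])
  fs1 <- selectTopWindows(f1, "Fst", topFraction)
  fs2 <- selectTopWindows(f2, "Fst", topFraction)
  zs1 <- selectTopWindows(z1, "negZHp", topFraction)
  zs2 <- selectTopWindows(z2, "negZHp", topFraction)
  fi <- SweepCallSet(
    "FST_INTERSECT",
    suppressWarnings(intersectScans(fs1$windows, fs2$windows)),
    c(fst1 = fs1$cutoff, fst2 = fs2$cutoff)
  )
  zi <- SweepCallSet(
    "ZHP_INTERSECT",
    suppressWarnings(intersectScans(zs1$windows, zs2$windows)),
    c(zhp1 = zs1$cutoff, zhp2 = zs2$cutoff)
  )
  list(
    final = finalOverlap(fi, zi), fstInt = fi, zhpInt = zi,
    nWindows = length(z1), scans = list(z1 = z1, z2 = z2, f1 = f1, f2 = f2)
  )
}
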