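## Distribute per-site error reads uniformly over the three nucleotides
## other than the source allele, fully vectorised (binomial chain).
.scatterErrors <- function(counts, srcIdx, E) {
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  e1 <- stats::rbinom(length(E), E, 1 / 3)
  e2 <- stats::rbinom(length(E), E - e1, 1 / 2)
  e3 <- E - e1 - e2
  i <- seq_along(E)
  counts[cbind(i, others[srcIdx, 1L])] <- counts[cbind(i, others[srcIdx, 1L])] + e1
  counts[cbind(i, others[srcIdx, 2L])] <- counts[cbind(i, others[srcIdx, 2L])] + e2
  counts[cbind(i, others[srcIdx, 3L])] <- counts[cbind(i, others[srcIdx, 3L])] + e3
  counts
}

#' Simulate a pooled-sequencing dataset with planted sweeps
#'
#' Generates per-pool per-site allele read counts with known truth. SNP
#' positions are drawn at the configured density; each site gets an
#' ancestral and a derived nucleotide and a baseline derived-allele
#' frequency drawn uniformly from \code{mafRange}, shared across pools up
#' to pool-specific Gaussian drift noise. Inside a planted sweep region
#' the target pools' derived-allele frequency is set to
#' \code{derived_freq} (reducing expected heterozygosity there and raising
#' divergence from non-target pools). Read depth per pool and site is
#' Poisson around the pool's mean depth, truncated to \code{[1, 3 mean]};
#' reads are binomial in the pool's true frequency, and each read is
#' miscalled as a uniformly chosen other nucleotide with probability
#' \code{errorRate}. The same seed always yields the identical dataset.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A list with \code{counts} (a \linkS4class{PoolCounts}),
#'   \code{truth} (data.frame: scaffold, position, ancestral, derived and
#'   one true derived-allele-frequency column per pool) and \code{sweeps}
#'   (\code{GRanges} of the planted regions with \code{target_pools} and
#'   \code{derived_freq}).
#' @examples
#' sim <- simulatePoolCounts(SimulationConfig(
#'   nScaffolds = 1, scaffoldLength = 50000, seed = 42
#' ))
#' sim$counts
#' @export
simulatePoolCounts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  scafNames <- sprintf("scaffold%02d", seq_len(config@nScaffolds))
  L <- config@scaffoldLength
  nPools <- nrow(config@pools)
  poolIds <- as.character(config@pools$pool_id)

  scaffold <- character()
  position <- integer()
  for (s in scafNames) {
    nSites <- stats::rbinom(1L, L, config@snpDensity)
    pos <- sort(sample.int(L, nSites))
    scaffold <- c(scaffold, rep(s, nSites))
    position <- c(position, pos)
  }
  n <- length(position)

  ancIdx <- sample.int(4L, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  derIdx <- ((ancIdx - 1L + shift) %% 4L) + 1L
  f0 <- stats::runif(n, config@mafRange[1L], config@mafRange[2L])

  freq <- matrix(NA_real_, n, nPools, dimnames = list(NULL, poolIds))
  for (k in seq_len(nPools)) {
    freq[, k] <- pmin(pmax(f0 + stats::rnorm(n, 0, config@driftSd), 0), 1)
  }

  sw <- config@sweepRegions
  if (nrow(sw)) {
    for (r in seq_len(nrow(sw))) {
      targets <- trimws(strsplit(sw$target_pools[r], ",")[[1L]])
      bad <- setdiff(targets, poolIds)
      if (length(bad)) stop("unknown sweep target pool: ", paste(bad, collapse = ","))
      inReg <- scaffold == sw$scaffold[r] &
        position >= sw$start[r] & position <= sw$end[r]
      if (!any(inReg)) {
        warning(sprintf(
          "sweep region %s:%d-%d contains no simulated site",
          sw$scaffold[r], sw$start[r], sw$end[r]
        ))
      }
      freq[inReg, targets] <- sw$derived_freq[r]
    }
  }

  counts <- array(0L, c(n, 6L, nPools),
    dimnames = list(NULL, SYNC_ALLELES, poolIds)
  )
  syncIdx <- match(NUC_ALLELES, SYNC_ALLELES) # A,C,G,T slots in sync order
  for (k in seq_len(nPools)) {
    md <- config@pools$mean_depth[k]
    depth <- pmin(pmax(stats::rpois(n, md), 1L), as.integer(3 * md))
    der <- stats::rbinom(n, depth, freq[, k])
    anc <- depth - der
    errA <- stats::rbinom(n, anc, config@errorRate)
    errD <- stats::rbinom(n, der, config@errorRate)
    nuc <- matrix(0L, n, 4L)
    i <- seq_len(n)
    nuc[cbind(i, ancIdx)] <- anc - errA
    nuc[cbind(i, derIdx)] <- nuc[cbind(i, derIdx)] + der - errD
    nuc <- .scatterErrors(nuc, ancIdx, errA)
    nuc <- .scatterErrors(nuc, derIdx, errD)
    counts[, syncIdx, k] <- nuc
  }

  sl <- structure(rep(L, length(scafNames)), names = scafNames)
  pc <- PoolCounts(scaffold, position, NUC_ALLELES[ancIdx], counts,
    poolNames = poolIds, seqlengths = sl
  )
  truth <- data.frame(
    scaffold = scaffold, position = position,
    ancestral = NUC_ALLELES[ancIdx], derived = NUC_ALLELES[derIdx],
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nPools)) truth[[paste0("freq_", poolIds[k])]] <- freq[, k]
  sweeps <- if (nrow(sw)) {
    GRanges(sw$scaffold, IRanges(sw$start, sw$end),
      target_pools = sw$target_pools, derived_freq = sw$derived_freq
    )
  } else {
    GRanges()
  }
  list(counts = pc, truth = truth, sweeps = sweeps)
}

#' Simulate a genotype count table
#'
#' Draws each group's genotype counts from a multinomial with the given
#' genotype probabilities; the structure mirrors a PCR-validation genotype
#' table (rows = genotypes, columns = groups).
#'
#' @param nPerGroup Named integer vector: individuals genotyped per group.
#' @param genotypeProbs Numeric matrix, genotypes x groups; each column
#'   must sum to 1. Row names are the genotype labels.
#' @param seed Optional integer seed for reproducibility.
#' @return An integer matrix of genotype counts.
#' @examples
#' p <- cbind(Gray = c(0.3, 0.6, 0.1), White = c(0.9, 0.1, 0))
#' rownames(p) <- c("GG", "GA", "AA")
#' simulateGenotypeTable(c(Gray = 100, White = 100), p, seed = 1)
#' @export
simulateGenotypeTable <- function(nPerGroup, genotypeProbs, seed = NULL) {
  genotypeProbs <- as.matrix(genotypeProbs)
  if (any(genotypeProbs < 0) || any(nPerGroup < 0)) {
    stop("counts and probabilities must be non-negative")
  }
  if (any(abs(colSums(genotypeProbs) - 1) > 1e-8)) {
    stop("each group's genotype probabilities must sum to 1")
  }
  stopifnot(length(nPerGroup) == ncol(genotypeProbs))
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_along(nPerGroup), function(g) {
    stats::rmultinom(1L, nPerGroup[g], genotypeProbs[, g])[, 1L]
  }, integer(nrow(genotypeProbs)))
  dimnames(out) <- list(
    rownames(genotypeProbs),
    if (!is.null(names(nPerGroup))) names(nPerGroup) else colnames(genotypeProbs)
  )
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the sync file, the per-site truth table (TSV) and a BED of the
#' planted sweep regions, the inputs the scan pipeline consumes.
#'
#' @param sim Result of \code{\link{simulatePoolCounts}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sync = file.path(dir, "pools.sync"),
    truth = file.path(dir, "truth.tsv"),
    sweeps = file.path(dir, "sweeps.bed")
  )
  writeSync(sim$counts, paths["sync"])
  utils::write.table(sim$truth, paths["truth"],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  sw <- sim$sweeps
  lines <- if (length(sw)) {
    sprintf(
      "%s\t%d\t%d\t%s", as.character(seqnames(sw)),
      start(sw) - 1L, end(sw), sw$target_pools
    )
  } else {
    character()
  }
  writeLines(lines, paths["sweeps"])
  invisible(paths)
}
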