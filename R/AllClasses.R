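#' @import methods
#' @importFrom GenomicRanges GRanges granges findOverlaps reduce seqnames
#'   start end width strand mcols mcols<-
#' @importFrom IRanges IRanges ranges subsetByOverlaps
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames
NULL

## Allele column order follows the sync format convention.
SYNC_ALLELES <- c("A", "T", "C", "G", "N", "del")

## Nucleotides that enter depth / allele-frequency computations ("N" and
## "del" are excluded: deletions are handled by the indel-proximity filter).
NUC_ALLELES <- c("A", "C", "G", "T")

#' PoolCounts: per-site allele read counts for one or more pools
#'
#' The central container of the package. Holds one genomic site per row
#' (a width-1 \link[GenomicRanges]{GRanges} with the reference base in
#' \code{mcols()$ref}) and an integer array of read counts with dimensions
#' sites x alleles (A, T, C, G, N, del) x pools. All window statistics
#' (pooled heterozygosity, F_ST) are computed from this object.
#'
#' Coordinates are 1-based inclusive throughout; BED input/output is
#' converted at the boundary.
#'
#' @slot sites A \code{GRanges} of width-1 positions, metadata column
#'   \code{ref} holding the reference base (A, C, G, T or N).
#' @slot counts Integer array \code{[nSites, 6, nPools]} with allele
#'   dimension named \code{A,T,C,G,N,del} (sync column order).
#' @slot poolNames Character vector naming the pools, one per array slice.
#'
#' @seealso \code{\link{readSync}}, \code{\link{simulatePoolCounts}},
#'   \code{\link{hpScan}}, \code{\link{fstScan}}
#' @export
setClass("PoolCounts",
  representation(
    sites = "GRanges",
    counts = "array",
    poolNames = "character"
  )
)

setValidity("PoolCounts", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) {
    return("'counts' must be a 3-d array (sites x alleles x pools)")
  }
  if (d[1L] != length(object@sites)) {
    msg <- c(msg, "number of count rows must equal number of sites")
  }
  if (d[2L] != 6L || !identical(dimnames(object@counts)[[2L]], SYNC_ALLELES)) {
    msg <- c(msg, "allele dimension must be named A,T,C,G,N,del")
  }
  if (d[3L] != length(object@poolNames)) {
    msg <- c(msg, "pool dimension must match length of poolNames")
  }
  if (anyDuplicated(object@poolNames)) {
    msg <- c(msg, "pool names must be unique")
  }
  if (length(object@counts) && min(object@counts, na.rm = TRUE) < 0) {
    msg <- c(msg, "all read counts must be >= 0")
  }
  if (length(object@sites) && is.null(object@sites$ref)) {
    msg <- c(msg, "'sites' must carry a 'ref' metadata column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PoolCounts object
#'
#' @param scaffold Character vector of scaffold/contig names, one per site.
#' @param position 1-based site positions.
#' @param ref Reference base per site (A, C, G, T or N).
#' @param counts Integer array \code{[nSites, 6, nPools]}, allele dimension
#'   in sync order A, T, C, G, N, del; or a list of per-pool sites x 6
#'   matrices.
#' @param poolNames Pool names; defaults to \code{pool1..poolK}.
#' @param seqlengths Optional named vector of scaffold lengths (used to clip
#'   trailing windows).
#' @return A \linkS4class{PoolCounts} object.
#' @examples
#' cnt <- array(0L, c(2, 6, 1), dimnames = list(NULL, syncAlleles(), NULL))
#' cnt[1, "A", 1] <- 30L; cnt[1, "G", 1] <- 10L
#' cnt[2, "C", 1] <- 44L
#' PoolCounts(c("sc1", "sc1"), c(100L, 200L), c("A", "C"), cnt)
#' @export
PoolCounts <- function(scaffold, position, ref, counts,
                       poolNames = NULL, seqlengths = NULL) {
  if (is.list(counts)) {
    counts <- array(unlist(counts, use.names = FALSE),
      dim = c(nrow(counts[[1L]]), 6L, length(counts))
    )
  }
  if (length(dim(counts)) != 3L) {
    stop("'counts' must be a sites x 6 x pools array")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, SYNC_ALLELES, poolNames)
  if (is.null(poolNames)) {
    poolNames <- sprintf("pool%d", seq_len(dim(counts)[3L]))
  }
  sites <- GRanges(scaffold, IRanges(position, width = 1L), ref = as.character(ref))
  if (!is.null(seqlengths)) {
    seqlengths(sites) <- seqlengths[seqlevels(sites)]
  }
  new("PoolCounts", sites = sites, counts = counts, poolNames = poolNames)
}

#' Sync-format allele order
#'
#' @return The character vector \code{c("A","T","C","G","N","del")}, the
#'   column order of count arrays and of sync pool columns.
#' @export
syncAlleles <- function() SYNC_ALLELES

#' Site filter parameters
#'
#' Parameters of the SNP site filter: per-pool depth bounds, minimum minor
#' allele frequency, minimum site quality and the exclusion distance around
#' indels. Defaults are the standard Pool-Seq settings (depth 10-100,
#' MAF 0.05, quality 20, 15 bp indel exclusion).
#'
#' @slot minDepth,maxDepth Per-pool read-depth bounds (inclusive).
#' @slot minMAF Minimum minor allele frequency in \code{[0, 0.5]}.
#' @slot minQuality Minimum phred-scaled site quality; only applied when
#'   qualities are supplied.
#' @slot indelExclusionBp Sites within this many bp of an indel (inclusive)
#'   are discarded.
#' @export
setClass("SiteFilterParams",
  representation(
    minDepth = "integer",
    maxDepth = "integer",
    minMAF = "numeric",
    minQuality = "numeric",
    indelExclusionBp = "integer"
  )
)

setValidity("SiteFilterParams", function(object) {
  msg <- character()
  if (object@minDepth > object@maxDepth) {
    msg <- c(msg, "minDepth must be <= maxDepth")
  }
  if (object@minMAF < 0 || object@minMAF > 0.5) {
    msg <- c(msg, "minMAF must lie in [0, 0.5]")
  }
  if (object@indelExclusionBp < 0) {
    msg <- c(msg, "indelExclusionBp must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SiteFilterParams-class
#' @param minDepth,maxDepth,minMAF,minQuality,indelExclusionBp See slots.
#' @return A \code{SiteFilterParams} object.
#' @examples
#' SiteFilterParams()
#' SiteFilterParams(minDepth = 20)
#' @export
SiteFilterParams <- function(minDepth = 10L, maxDepth = 100L, minMAF = 0.05,
                             minQuality = 20, indelExclusionBp = 15L) {
  new("SiteFilterParams",
    minDepth = as.integer(minDepth), maxDepth = as.integer(maxDepth),
    minMAF = minMAF, minQuality = minQuality,
    indelExclusionBp = as.integer(indelExclusionBp)
  )
}

#' SweepCallSet: windows surviving a sweep-detection step
#'
#' Records which windows survived one step of the three-step sweep
#' procedure (per-comparison F_ST intersection, per-pool -ZHp intersection,
#' or the final overlap of the two), together with the thresholds used and,
#' for the final step, the merged contiguous regions.
#'
#' @slot step One of \code{"FST_INTERSECT"}, \code{"ZHP_INTERSECT"},
#'   \code{"FINAL_OVERLAP"}.
#' @slot windows \code{GRanges} of surviving windows; metadata columns carry
#'   the statistic values of every contributing scan.
#' @slot regions \code{GRanges} of maximal runs of adjacent surviving
#'   windows (populated for the final step; otherwise mirrors windows).
#' @slot thresholds Named numeric: the top-quantile cutoff of each
#'   contributing scan.
#' @export
setClass("SweepCallSet",
  representation(
    step = "character",
    windows = "GRanges",
    regions = "GRanges",
    thresholds = "numeric"
  )
)

setValidity("SweepCallSet", function(object) {
  ok <- c("FST_INTERSECT", "ZHP_INTERSECT", "FINAL_OVERLAP")
  if (!(length(object@step) == 1L && object@step %in% ok)) {
    return(sprintf("'step' must be one of %s", paste(ok, collapse = ", ")))
  }
  TRUE
})

#' Simulation configuration for synthetic Pool-Seq data
#'
#' Describes a synthetic pooled-sequencing experiment: scaffold layout, SNP
#' density, the pools (diploid sample size and mean sequencing depth), the
#' planted sweep regions, the baseline minor-allele-frequency range, the
#' pool-specific drift noise and the per-read sequencing error rate. The
#' defaults mirror a three-pool design of 117, 25 and 87 diploids sequenced
#' to ~44x, one gray reference pool and two white pools.
#'
#' @slot nScaffolds,scaffoldLength Number of scaffolds and their common
#'   length in bp.
#' @slot snpDensity Expected SNPs per bp.
#' @slot pools data.frame with columns \code{pool_id}, \code{n_diploids},
#'   \code{mean_depth}.
#' @slot sweepRegions data.frame with columns \code{scaffold}, \code{start},
#'   \code{end}, \code{target_pools} (comma-separated pool ids) and
#'   \code{derived_freq} in (0.5, 1].
#' @slot mafRange Baseline minor-allele-frequency range, drawn uniformly.
#' @slot driftSd Standard deviation of pool-specific allele-frequency noise.
#' @slot errorRate Per-read probability of a sequencing error (read reported
#'   as a uniformly chosen different nucleotide).
#' @slot seed Integer random seed; identical seeds give identical datasets.
#' @export
setClass("SimulationConfig",
  representation(
    nScaffolds = "integer",
    scaffoldLength = "integer",
    snpDensity = "numeric",
    pools = "data.frame",
    sweepRegions = "data.frame",
    mafRange = "numeric",
    driftSd = "numeric",
    errorRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  p <- object@pools
  if (!all(c("pool_id", "n_diploids", "mean_depth") %in% names(p))) {
    msg <- c(msg, "pools must have columns pool_id, n_diploids, mean_depth")
  } else if (any(p$mean_depth <= 0) || any(p$n_diploids <= 0)) {
    msg <- c(msg, "pool sizes and mean depths must be positive")
  }
  sw <- object@sweepRegions
  if (nrow(sw)) {
    need <- c("scaffold", "start", "end", "target_pools", "derived_freq")
    if (!all(need %in% names(sw))) {
      msg <- c(msg, "sweepRegions must have columns scaffold, start, end, target_pools, derived_freq")
    } else {
      if (any(sw$start < 1) || any(sw$end > object@scaffoldLength) ||
        any(sw$start > sw$end)) {
        msg <- c(msg, "sweep regions must lie within scaffold bounds")
      }
      if (any(sw$derived_freq <= 0.5) || any(sw$derived_freq > 1)) {
        msg <- c(msg, "derived_freq must lie in (0.5, 1]")
      }
    }
  }
  if (length(object@mafRange) != 2L || object@mafRange[1L] > object@mafRange[2L] ||
    object@mafRange[1L] < 0 || object@mafRange[2L] > 0.5) {
    msg <- c(msg, "mafRange must be an increasing pair within [0, 0.5]")
  }
  if (object@snpDensity <= 0 || object@snpDensity > 1) {
    msg <- c(msg, "snpDensity must lie in (0, 1]")
  }
  if (object@errorRate < 0 || object@errorRate >= 1) {
    msg <- c(msg, "errorRate must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nScaffolds,scaffoldLength,snpDensity,pools,sweepRegions,mafRange,driftSd,errorRate,seed
#'   See the class slots.
#' @return A \code{SimulationConfig} object.
#' @examples
#' cfg <- SimulationConfig(nScaffolds = 1, scaffoldLength = 1e5, seed = 7)
#' @export
SimulationConfig <- function(nScaffolds = 5L,
                             scaffoldLength = 1000000L,
                             snpDensity = 0.002,
                             pools = data.frame(
                               pool_id = c("gray", "white1", "white2"),
                               n_diploids = c(117L, 25L, 87L),
                               mean_depth = c(44, 44, 44)
                             ),
                             sweepRegions = data.frame(
                               scaffold = character(), start = integer(),
                               end = integer(), target_pools = character(),
                               derived_freq = numeric()
                             ),
                             mafRange = c(0.05, 0.5),
                             driftSd = 0.02,
                             errorRate = 0.001,
                             seed = 1L) {
  new("SimulationConfig",
    nScaffolds = as.integer(nScaffolds),
    scaffoldLength = as.integer(scaffoldLength),
    snpDensity = snpDensity,
    pools = pools,
    sweepRegions = sweepRegions,
    mafRange = as.numeric(mafRange),
    driftSd = driftSd,
    errorRate = errorRate,
    seed = as.integer(seed)
  )
}
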