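## Per-site Weir-Cockerham variance components for two populations, in the
## allele-frequency (ANOVA on allele indicators) form. With allele sample
## sizes n1, n2 and allele-1 frequencies p1, p2:
##   MSP = n1 (p1 - pbar)^2 + n2 (p2 - pbar)^2          (between, r-1 = 1)
##   MSG = (n1 p1 (1-p1) + n2 p2 (1-p2)) / (n1 + n2 - 2) (within)
##   nc  = n1 + n2 - (n1^2 + n2^2) / (n1 + n2)
## theta = (MSP - MSG) / (MSP + (nc - 1) MSG); windows combine components
## as a ratio of sums.
.wcComponents <- function(p1, p2, n1, n2) {
  N <- n1 + n2
  bad <- N <= 2
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - 2)
  nc <- N - (n1^2 + n2^2) / N
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  list(num = num, den = den)
}

#' Weir-Cockerham F_ST of one window from pooled read counts
#'
#' Computes the two-population Weir-Cockerham \eqn{F_{ST}} estimator on
#' allele frequencies derived from read counts, with the effective allele
#' sample size of each pool capped at its haploid pool size
#' (\code{n = min(read depth, haploid pool size)}). Per-site variance
#' components are combined over the window as a ratio of sums. The
#' estimator is reported as computed: it can be negative under no
#' differentiation and is not clamped.
#'
#' @param countsA,countsB Integer matrices (sites x 2) of read counts of
#'   allele 1 and allele 2 in each pool; rows are paired sites with the
#'   same allele labelling in both pools.
#' @param poolSizes Numeric length-2 vector of haploid pool sizes
#'   (chromosomes) for pools A and B.
#' @return The window \eqn{F_{ST}} value, or \code{NA_real_} when no site
#'   is usable.
#' @examples
#' # one site, depths 50/50, allele-1 frequencies 0.9 and 0.1
#' fstWindow(cbind(45, 5), cbind(5, 45), c(100, 100))
#' @export
fstWindow <- function(countsA, countsB, poolSizes) {
  countsA <- rbind(countsA)
  countsB <- rbind(countsB)
  stopifnot(
    ncol(countsA) == 2L, ncol(countsB) == 2L,
    nrow(countsA) == nrow(countsB), length(poolSizes) == 2L
  )
  if (any(poolSizes <= 0)) stop("pool sizes must be positive")
  if (!nrow(countsA)) {
    return(NA_real_)
  }
  dA <- rowSums(countsA)
  dB <- rowSums(countsB)
  use <- dA > 0 & dB > 0
  if (!any(use)) {
    return(NA_real_)
  }
  p1 <- countsA[use, 1L] / dA[use]
  p2 <- countsB[use, 1L] / dB[use]
  n1 <- pmin(dA[use], poolSizes[1L])
  n2 <- pmin(dB[use], poolSizes[2L])
  comp <- .wcComponents(p1, p2, n1, n2)
  num <- sum(comp$num, na.rm = TRUE)
  den <- sum(comp$den, na.rm = TRUE)
  if (den == 0 || all(is.na(comp$den))) {
    return(NA_real_)
  }
  num / den
}

#' Windowed F_ST scan between two pools
#'
#' Runs the Weir-Cockerham window \eqn{F_{ST}} (see
#' \code{\link{fstWindow}}) over the fixed tiling for one pair of pools.
#' At each site the biallelic pair is the two most abundant nucleotides of
#' the two pools combined (ties broken A < C < G < T); only sites with
#' non-zero depth in both pools are used, so the tiling matches the Hp
#' scan's but window SNP counts can differ.
#'
#' @param x A \linkS4class{PoolCounts} object (normally filtered).
#' @param poolA,poolB Pool names or indices.
#' @param poolSizes Haploid pool sizes (chromosomes) of A and B.
#' @param windowSize Window width in bp (default 10000).
#' @param minSnps Minimum shared SNPs per retained window (default 10).
#' @return A \code{GRanges} of retained windows with metadata columns
#'   \code{snpCount}, \code{Fst}, \code{pair}.
#' @export
fstScan <- function(x, poolA, poolB, poolSizes, windowSize = 10000L,
                    minSnps = 10L) {
  stopifnot(is(x, "PoolCounts"), length(poolSizes) == 2L)
  if (any(poolSizes <= 0)) stop("pool sizes must be positive")
  cmA <- .nucMatrix(x, poolA)
  cmB <- .nucMatrix(x, poolB)
  shared <- rowSums(cmA) > 0L & rowSums(cmB) > 0L
  xs <- x[shared]
  cmA <- cmA[shared, , drop = FALSE]
  cmB <- cmB[shared, , drop = FALSE]
  mm <- .majMin(cmA + cmB)
  i <- seq_len(nrow(cmA))
  a1 <- cbind(i, mm$majIdx)
  a2 <- cbind(i, mm$minIdx)
  countsA <- cbind(cmA[a1], cmA[a2])
  countsB <- cbind(cmB[a1], cmB[a2])
  win <- makeWindows(xs, windowSize = windowSize, minSnps = minSnps)
  idx <- mcols(win)$siteIdx
  fst <- vapply(seq_along(win), function(w) {
    j <- idx[[w]]
    fstWindow(
      countsA[j, , drop = FALSE], countsB[j, , drop = FALSE],
      poolSizes
    )
  }, numeric(1L))
  mcols(win)$siteIdx <- NULL
  mcols(win)$Fst <- fst
  nmA <- if (is.character(poolA)) poolA else poolNames(x)[poolA]
  nmB <- if (is.character(poolB)) poolB else poolNames(x)[poolB]
  mcols(win)$pair <- paste(nmA, nmB, sep = "_vs_")
  win
}
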