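## Major/minor allele bookkeeping, vectorised over a sites x 4 (A,C,G,T)
## count matrix. Ties are broken by fixed allele order A < C < G < T.
.majMin <- function(cm) {
  if (!nrow(cm)) {
    return(list(
      majIdx = integer(), minIdx = integer(),
      nMaj = integer(), nMin = integer()
    ))
  }
  majIdx <- max.col(cm, ties.method = "first")
  sel <- cbind(seq_len(nrow(cm)), majIdx)
  nMaj <- cm[sel]
  cm2 <- cm
  cm2[sel] <- -1L
  minIdx <- max.col(cm2, ties.method = "first")
  nMin <- cm2[cbind(seq_len(nrow(cm2)), minIdx)]
  list(majIdx = majIdx, minIdx = minIdx, nMaj = nMaj, nMin = pmax(nMin, 0L))
}

.nucMatrix <- function(x, pool) {
  alleleCounts(x, pool)[, NUC_ALLELES, drop = FALSE]
}

#' Per-site allele frequencies from read depths
#'
#' For each site in one pool, identifies the most and least abundant
#' nucleotide alleles and their read counts (\code{nMaj}, \code{nMin}), and
#' the minor allele frequency \code{maf = nMin / (nMaj + nMin)}. Only the
#' two most abundant alleles enter \code{maf}. A monomorphic site has
#' \code{nMin = 0}, \code{maf = 0} and a missing minor allele. Ties for the
#' major allele are broken by fixed allele order A < C < G < T.
#'
#' @param x A \linkS4class{PoolCounts} object.
#' @param pool Pool name or index.
#' @return A \code{data.frame} with columns \code{scaffold},
#'   \code{position}, \code{major}, \code{minor}, \code{nMaj}, \code{nMin},
#'   \code{maf}.
#' @examples
#' cnt <- array(0L, c(1, 6, 1), dimnames = list(NULL, syncAlleles(), NULL))
#' cnt[1, "A", 1] <- 30L; cnt[1, "G", 1] <- 10L
#' pc <- PoolCounts("sc1", 100L, "A", cnt)
#' siteAlleleFreq(pc, 1) # maf = 0.25
#' @export
siteAlleleFreq <- function(x, pool) {
  cm <- .nucMatrix(x, pool)
  tot <- rowSums(cm)
  if (any(tot == 0L)) {
    stop(
      "undefined site (all-zero nucleotide counts) at row ",
      which(tot == 0L)[1L]
    )
  }
  mm <- .majMin(cm)
  data.frame(
    scaffold = as.character(seqnames(x@sites)),
    position = start(x@sites),
    major = NUC_ALLELES[mm$majIdx],
    minor = ifelse(mm$nMin > 0L, NUC_ALLELES[mm$minIdx], NA_character_),
    nMaj = mm$nMaj,
    nMin = mm$nMin,
    maf = mm$nMin / (mm$nMaj + mm$nMin),
    stringsAsFactors = FALSE
  )
}

.checkSorted <- function(sites) {
  sc <- as.character(seqnames(sites))
  pos <- start(sites)
  r <- rle(sc)
  if (anyDuplicated(r$values)) {
    stop("sites must be grouped by scaffold (scaffolds are interleaved)")
  }
  splitpos <- split(pos, factor(sc, levels = r$values))
  if (any(vapply(splitpos, is.unsorted, logical(1L)))) {
    stop("sites must be sorted by position within each scaffold")
  }
  invisible(TRUE)
}

#' Filter SNP sites on depth, quality, MAF and indel proximity
#'
#' Applies the standard Pool-Seq site filter: a site is retained iff every
#' pool's nucleotide read depth lies in \code{[minDepth, maxDepth]}, the
#' site quality (when supplied) is at least \code{minQuality}, the minor
#' allele frequency computed from counts summed over all pools is at least
#' \code{minMAF}, and no indel lies within \code{indelExclusionBp} bp
#' (boundary inclusive). Rejections are attributed to the first failing
#' check in the order depth, quality, MAF, indel.
#'
#' MAF is evaluated on the pooled counts so that a site fixed in one pool
#' but segregating overall (the signature of a selective sweep) is kept.
#'
#' @param x A \linkS4class{PoolCounts} object, sites sorted by scaffold and
#'   position.
#' @param params A \linkS4class{SiteFilterParams} object.
#' @param indels Indel positions: a \code{GRanges}, or a named list of
#'   per-scaffold integer position vectors. \code{NULL} disables the check.
#' @param quality Optional numeric vector of phred-scaled site qualities
#'   (one per site). When \code{NULL} the quality check is skipped and the
#'   skipped count reported in the tally.
#' @return A list with elements \code{counts} (the retained
#'   \code{PoolCounts}), \code{keep} (logical vector), and \code{tally}
#'   (named counts: retained, depth, quality, maf, indel,
#'   quality_unavailable).
#' @export
filterSites <- function(x, params = SiteFilterParams(), indels = NULL,
                        quality = NULL) {
  stopifnot(is(x, "PoolCounts"), is(params, "SiteFilterParams"))
  .checkSorted(x@sites)
  n <- length(x)
  if (!n) {
    return(list(
      counts = x, keep = logical(),
      tally = c(
        retained = 0L, depth = 0L, quality = 0L, maf = 0L, indel = 0L,
        quality_unavailable = 0L
      )
    ))
  }
  d <- depths(x)
  depth_ok <- rowSums(d < params@minDepth | d > params@maxDepth) == 0L

  if (is.null(quality)) {
    qual_ok <- rep(TRUE, n)
    qual_na <- n
  } else {
    stopifnot(length(quality) == n)
    qual_ok <- quality >= params@minQuality
    qual_na <- 0L
  }

  cmTot <- .nucMatrix(x, 1L)
  for (k in seq_along(x@poolNames)[-1L]) {
    cmTot <- cmTot + .nucMatrix(x, k)
  }
  mm <- .majMin(cmTot)
  tot2 <- mm$nMaj + mm$nMin
  maf <- ifelse(tot2 > 0L, mm$nMin / tot2, 0)
  maf_ok <- maf >= params@minMAF

  if (is.null(indels)) {
    indel_ok <- rep(TRUE, n)
  } else {
    if (!is(indels, "GRanges")) {
      indels <- GRanges(
        rep(names(indels), lengths(indels)),
        IRanges(unlist(indels, use.names = FALSE), width = 1L)
      )
    }
    excl <- GRanges(
      seqnames(indels),
      IRanges(
        pmax(1L, start(indels) - params@indelExclusionBp),
        end(indels) + params@indelExclusionBp
      )
    )
    indel_ok <- GenomicRanges::countOverlaps(granges(x@sites), excl) == 0L
  }

  reason <- rep(NA_character_, n)
  reason[!indel_ok] <- "indel"
  reason[!maf_ok] <- "maf"
  reason[!qual_ok] <- "quality"
  reason[!depth_ok] <- "depth"
  keep <- is.na(reason)
  tally <- c(
    retained = sum(keep),
    depth = sum(reason == "depth", na.rm = TRUE),
    quality = sum(reason == "quality", na.rm = TRUE),
    maf = sum(reason == "maf", na.rm = TRUE),
    indel = sum(reason == "indel", na.rm = TRUE),
    quality_unavailable = qual_na
  )
  list(counts = x[keep], keep = keep, tally = tally)
}
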