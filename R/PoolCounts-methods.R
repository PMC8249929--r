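#' @describeIn PoolCounts-class Pool names.
#' @export
setMethod("poolNames", "PoolCounts", function(x) x@poolNames)

#' @describeIn PoolCounts-class The sites as a width-1 \code{GRanges} with a
#'   \code{ref} metadata column.
#' @export
setMethod("siteRanges", "PoolCounts", function(x) x@sites)

#' @describeIn PoolCounts-class Allele count matrix (sites x 6) of one pool,
#'   or the full 3-d array when \code{pool} is \code{NULL}.
#' @export
setMethod("alleleCounts", "PoolCounts", function(x, pool = NULL) {
  if (is.null(pool)) {
    return(x@counts)
  }
  if (is.character(pool)) {
    pool <- match(pool, x@poolNames)
    if (anyNA(pool)) stop("unknown pool name")
  }
  m <- x@counts[, , pool, drop = FALSE]
  matrix(m,
    nrow = dim(m)[1L], ncol = 6L,
    dimnames = list(NULL, SYNC_ALLELES)
  )
})

#' @describeIn PoolCounts-class Read depth per site and pool, summed over
#'   the nucleotide alleles A, C, G, T only ("N" and "del" excluded).
#' @export
setMethod("depths", "PoolCounts", function(x) {
  d <- apply(x@counts[, NUC_ALLELES, , drop = FALSE], c(1L, 3L), sum)
  dim(d) <- c(dim(x@counts)[1L], dim(x@counts)[3L])
  colnames(d) <- x@poolNames
  d
})

#' @describeIn PoolCounts-class Number of sites.
#' @export
setMethod("length", "PoolCounts", function(x) length(x@sites))

#' @describeIn PoolCounts-class Subset sites.
#' @param i Site index (logical or integer).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "PoolCounts", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    sites = x@sites[i],
    counts = x@counts[i, , , drop = FALSE],
    poolNames = x@poolNames
  )
})

setMethod("show", "PoolCounts", function(object) {
  cat(
    "PoolCounts:", length(object@sites), "sites,",
    length(object@poolNames), "pools (",
    paste(object@poolNames, collapse = ", "), ")\n"
  )
  if (length(object@sites)) {
    sc <- as.character(seqnames(object@sites))
    cat(" scaffolds:", length(unique(sc)), "\n")
    d <- depths(object)
    cat(" mean depth per pool:", paste(round(colMeans(d), 1), collapse = ", "), "\n")
  }
})

#' @describeIn SweepCallSet-class Which procedure step produced the calls.
#' @export
setMethod("sweepStep", "SweepCallSet", function(x) x@step)

#' @describeIn SweepCallSet-class Surviving windows with the statistic
#'   values of every contributing scan.
#' @export
setMethod("sweepWindows", "SweepCallSet", function(x) x@windows)

#' @describeIn SweepCallSet-class Maximal runs of adjacent surviving windows.
#' @export
setMethod("sweepRegions", "SweepCallSet", function(x) x@regions)

#' @describeIn SweepCallSet-class Named vector of per-scan cutoffs.
#' @export
setMethod("thresholds", "SweepCallSet", function(x) x@thresholds)

setMethod("show", "SweepCallSet", function(object) {
  cat(
    "SweepCallSet [", object@step, "]: ", length(object@windows),
    " windows in ", length(object@regions), " regions\n",
    sep = ""
  )
  if (length(object@thresholds)) {
    cat(" thresholds:\n")
    for (nm in names(object@thresholds)) {
      cat(sprintf("  %s >= %.6g\n", nm, object@thresholds[[nm]]))
    }
  }
})
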