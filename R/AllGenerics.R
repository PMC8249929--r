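#' @rdname PoolCounts-class
#' @param x,object A \code{PoolCounts} or \code{SweepCallSet} object.
#' @export
setGeneric("poolNames", function(x) standardGeneric("poolNames"))

#' @rdname PoolCounts-class
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname PoolCounts-class
#' @param pool Pool name or index; \code{NULL} returns all pools.
#' @export
setGeneric("alleleCounts", function(x, pool = NULL) standardGeneric("alleleCounts"))

#' @rdname PoolCounts-class
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname SweepCallSet-class
#' @export
setGeneric("sweepStep", function(x) standardGeneric("sweepStep"))

#' @rdname SweepCallSet-class
#' @export
setGeneric("sweepWindows", function(x) standardGeneric("sweepWindows"))

#' @rdname SweepCallSet-class
#' @export
setGeneric("sweepRegions", function(x) standardGeneric("sweepRegions"))

#' @rdname SweepCallSet-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
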