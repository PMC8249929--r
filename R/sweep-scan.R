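.windowKey <- function(gr) {
  paste(as.character(seqnames(gr)), start(gr), end(gr), sep = "\r")
}

#' Intersect two selected window sets on the same tiling
#'
#' Returns the windows present in both sets, matched exactly by
#' (scaffold, start, end). Both inputs must come from the same window
#' tiling: any pair of windows that overlap without being identical is a
#' tiling mismatch and raises an error. The result carries the metadata
#' columns of both inputs (names made unique), so each surviving window
#' keeps the statistic values of every contributing scan. The operation is
#' commutative up to metadata column order.
#'
#' @param a,b \code{GRanges} window sets (e.g. the top-quantile selections
#'   of two scans).
#' @return A \code{GRanges} of the shared windows.
#' @export
intersectScans <- function(a, b) {
  ov <- findOverlaps(granges(a), granges(b))
  qi <- queryHits(ov)
  si <- subjectHits(ov)
  same <- start(a)[qi] == start(b)[si] & end(a)[qi] == end(b)[si] &
    as.character(seqnames(a))[qi] == as.character(seqnames(b))[si]
  if (any(!same)) {
    stop("window tilings are incompatible: overlapping but non-identical windows")
  }
  if (!length(qi)) {
    warning("scan intersection is empty")
    out <- granges(a)[integer()]
    mcols(out) <- cbind(mcols(a)[integer(), , drop = FALSE],
      mcols(b)[integer(), , drop = FALSE])
    names(mcols(out)) <- make.unique(names(mcols(out)))
    return(out)
  }
  out <- granges(a)[qi]
  mc <- cbind(mcols(a)[qi, , drop = FALSE], mcols(b)[si, , drop = FALSE])
  names(mc) <- make.unique(names(mc))
  mcols(out) <- mc
  o <- order(as.character(seqnames(out)), start(out), method = "radix")
  out[o]
}

#' Construct a SweepCallSet
#'
#' Wraps a window set produced by one step of the sweep-detection
#' procedure, computing the merged contiguous regions (maximal runs of
#' adjacent windows) for reporting.
#'
#' @param step \code{"FST_INTERSECT"}, \code{"ZHP_INTERSECT"} or
#'   \code{"FINAL_OVERLAP"}.
#' @param windows \code{GRanges} of surviving windows.
#' @param thresholds Named numeric vector of per-scan cutoffs.
#' @return A \linkS4class{SweepCallSet}.
#' @export
SweepCallSet <- function(step, windows, thresholds = numeric()) {
  regions <- reduce(granges(windows))
  new("SweepCallSet",
    step = step, windows = windows, regions = regions,
    thresholds = thresholds
  )
}

#' Final overlap of the F_ST and -ZHp candidate window sets
#'
#' The last step of the three-step sweep procedure: windows that survived
#' both the per-comparison F_ST intersection and the per-pool -ZHp
#' intersection. Adjacent surviving windows are merged into contiguous
#' regions for reporting; the window list is retained.
#'
#' @param fstCalls,zhpCalls \linkS4class{SweepCallSet} objects (or raw
#'   \code{GRanges} window sets) from the two preceding steps.
#' @return A \linkS4class{SweepCallSet} with \code{step = "FINAL_OVERLAP"}.
#' @export
finalOverlap <- function(fstCalls, zhpCalls) {
  wA <- if (is(fstCalls, "SweepCallSet")) sweepWindows(fstCalls) else fstCalls
  wB <- if (is(zhpCalls, "SweepCallSet")) sweepWindows(zhpCalls) else zhpCalls
  th <- c(
    if (is(fstCalls, "SweepCallSet")) thresholds(fstCalls) else NULL,
    if (is(zhpCalls, "SweepCallSet")) thresholds(zhpCalls) else NULL
  )
  windows <- if (length(wA) && length(wB)) {
    suppressWarnings(intersectScans(wA, wB))
  } else {
    granges(wA)[integer()]
  }
  SweepCallSet("FINAL_OVERLAP", windows, th)
}

#' Genes overlapping sweep regions, with flanking sequence
#'
#' A gene is hit when a final sweep region intersects the gene's span
#' extended by \code{flankBp} on both sides (clipped at position 1);
#' boundaries are inclusive. Each hit lists the contributing regions and,
#' when the call set's windows carry statistic values, the min/max of each
#' statistic over the windows overlapping the flanked gene.
#'
#' @param calls A \linkS4class{SweepCallSet} (or \code{GRanges} of
#'   regions).
#' @param genes \code{GRanges} of gene models with a \code{gene_id}
#'   metadata column (see \code{\link{readGenes}}).
#' @param flankBp Flank width in bp (default 10000).
#' @return A \code{data.frame} with one row per hit gene: \code{gene_id},
#'   \code{scaffold}, \code{gene_start}, \code{gene_end}, \code{n_regions},
#'   \code{regions}, and \code{<stat>_min}/\code{<stat>_max} columns;
#'   sorted by scaffold then gene start.
#' @export
overlapGenes <- function(calls, genes, flankBp = 10000L) {
  regions <- if (is(calls, "SweepCallSet")) sweepRegions(calls) else granges(calls)
  windows <- if (is(calls, "SweepCallSet")) sweepWindows(calls) else NULL
  empty <- data.frame(
    gene_id = character(), scaffold = character(),
    gene_start = integer(), gene_end = integer(),
    n_regions = integer(), regions = character(),
    stringsAsFactors = FALSE
  )
  if (!length(genes) || !length(regions)) {
    return(empty)
  }
  # strip seqinfo so annotation and scan scaffold universes need not match
  regions <- GRanges(as.character(seqnames(regions)), ranges(regions))
  if (!is.null(windows)) {
    mc <- mcols(windows)
    windows <- GRanges(as.character(seqnames(windows)), ranges(windows))
    mcols(windows) <- mc
  }
  flanked <- GRanges(
    as.character(seqnames(genes)),
    IRanges(pmax(1L, start(genes) - flankBp), end(genes) + flankBp)
  )
  ov <- findOverlaps(flanked, regions)
  if (!length(ov)) {
    return(empty)
  }
  hitGenes <- unique(queryHits(ov))
  rows <- lapply(hitGenes, function(g) {
    ri <- subjectHits(ov)[queryHits(ov) == g]
    reg <- regions[ri]
    row <- data.frame(
      gene_id = genes$gene_id[g],
      scaffold = as.character(seqnames(genes))[g],
      gene_start = start(genes)[g],
      gene_end = end(genes)[g],
      n_regions = length(reg),
      regions = paste(sprintf(
        "%s:%d-%d", as.character(seqnames(reg)), start(reg), end(reg)
      ), collapse = ","),
      stringsAsFactors = FALSE
    )
    if (!is.null(windows) && length(windows)) {
      wov <- findOverlaps(flanked[g], windows)
      wi <- subjectHits(wov)
      for (cn in names(mcols(windows))) {
        vals <- mcols(windows)[[cn]]
        if (is.numeric(vals) && !startsWith(cn, "snpCount") && length(wi)) {
          row[[paste0(cn, "_min")]] <- min(vals[wi])
          row[[paste0(cn, "_max")]] <- max(vals[wi])
        }
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$scaffold, out$gene_start), , drop = FALSE]
}
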