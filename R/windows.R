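## Window assignment: a site at 1-based position p on a tiling anchored at
## position 1 with width w belongs to window index ceiling(p / w), i.e.
## position 10000 falls in window 1 and 10001 in window 2 for w = 10000.
.windowIndex <- function(position, windowSize) {
  as.integer((position - 1L) %/% windowSize)
}

.windowGRanges <- function(scaffold, widx, windowSize, seqlens = NULL) {
  start <- widx * windowSize + 1L
  end <- (widx + 1L) * as.integer(windowSize)
  if (!is.null(seqlens) && length(seqlens)) {
    sl <- seqlens[scaffold]
    clip <- !is.na(sl) & end > sl
    end[clip] <- as.integer(sl[clip])
  }
  GRanges(scaffold, IRanges(start, end))
}

#' Tile sites into non-overlapping genomic windows
#'
#' Builds the fixed non-overlapping window tiling used by all scans:
#' windows of \code{windowSize} bp anchored at scaffold position 1
#' (\code{[1, w]}, \code{[w+1, 2w]}, ...). Only windows containing at least
#' one site are materialised; windows with fewer than \code{minSnps} sites
#' are discarded (their number is recorded in
#' \code{metadata()$n_discarded}). A trailing partial window at a scaffold
#' end (known from \code{seqlengths}) is clipped and kept if it meets
#' \code{minSnps}.
#'
#' @param scaffold Character vector of scaffold names, one per site, or a
#'   \linkS4class{PoolCounts} object (then \code{position} is ignored).
#' @param position Integer 1-based site positions.
#' @param windowSize Window width in bp (default 10000).
#' @param minSnps Minimum SNPs per retained window (default 10).
#' @param seqlengths Optional named scaffold lengths for clipping.
#' @return A \code{GRanges} of retained windows with metadata columns
#'   \code{snpCount} and \code{siteIdx} (an IntegerList of member site
#'   indices into the input).
#' @export
makeWindows <- function(scaffold, position = NULL, windowSize = 10000L,
                        minSnps = 10L, seqlengths = NULL) {
  if (is(scaffold, "PoolCounts")) {
    pc <- scaffold
    position <- start(pc@sites)
    if (is.null(seqlengths)) {
      sl <- seqlengths(pc@sites)
      if (any(!is.na(sl))) seqlengths <- sl
    }
    scaffold <- as.character(seqnames(pc@sites))
  }
  stopifnot(windowSize > 0L, length(scaffold) == length(position))
  widx <- .windowIndex(position, windowSize)
  key <- paste(scaffold, widx, sep = "\r")
  grp <- match(key, unique(key))
  cnt <- tabulate(grp)
  first <- !duplicated(key)
  gr <- .windowGRanges(scaffold[first], widx[first], windowSize, seqlengths)
  mcols(gr)$snpCount <- cnt
  mcols(gr)$siteIdx <- IRanges::IntegerList(split(seq_along(grp), grp))
  keep <- cnt >= minSnps
  out <- gr[keep]
  o <- order(as.character(seqnames(out)), start(out), method = "radix")
  out <- out[o]
  metadata(out)$n_discarded <- sum(!keep)
  out
}

#' Top-quantile threshold of a scan statistic
#'
#' Computes the cutoff for the upper tail of a window-statistic
#' distribution at \code{topFraction} (default the top 3\%) and selects
#' the windows at or above it. The cutoff is the empirical quantile at
#' probability \code{1 - topFraction} under the "higher" interpolation
#' rule (the sorted value at index \code{ceiling((n-1)(1-f) + 1)}), so for
#' values 1..100 and \code{topFraction = 0.03} the cutoff is 98. Values
#' tied with the cutoff are all selected.
#'
#' @param values Numeric window statistic values (NAs dropped).
#' @param topFraction Upper-tail fraction in (0, 1).
#' @return A list with \code{cutoff} (numeric) and \code{selected}
#'   (logical, parallel to \code{values}; \code{NA} values are never
#'   selected).
#' @examples
#' topQuantileThreshold(1:100, 0.03) # cutoff 98, selects 98, 99, 100
#' @export
topQuantileThreshold <- function(values, topFraction = 0.03) {
  stopifnot(topFraction > 0, topFraction < 1)
  ok <- !is.na(values)
  v <- values[ok]
  n <- length(v)
  if (n == 0L) stop("no defined statistic values")
  if (n == 1L) {
    warning("single window: degenerate top-quantile selection")
    return(list(cutoff = v, selected = ok))
  }
  if (diff(range(v)) == 0) {
    stop("all statistic values identical: distribution has no tail")
  }
  srt <- sort(v)
  idx <- ceiling((n - 1) * (1 - topFraction) + 1)
  cutoff <- srt[min(idx, n)]
  selected <- !is.na(values) & values >= cutoff
  list(cutoff = cutoff, selected = selected)
}

#' @rdname topQuantileThreshold
#' @param windows A \code{GRanges} of windows.
#' @param column Metadata column holding the statistic.
#' @return For \code{selectTopWindows}: a list with \code{cutoff} and
#'   \code{windows} (the selected subset).
#' @export
selectTopWindows <- function(windows, column, topFraction = 0.03) {
  th <- topQuantileThreshold(mcols(windows)[[column]], topFraction)
  list(cutoff = th$cutoff, windows = windows[th$selected])
}
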