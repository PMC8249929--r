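#' Pooled heterozygosity of one window
#'
#' The pooled-heterozygosity score of a window is
#' \deqn{Hp = \frac{2 \sum n_{MAJ} \sum n_{MIN}}{(\sum n_{MAJ} + \sum n_{MIN})^2}}
#' where \eqn{n_{MAJ}} and \eqn{n_{MIN}} are the read counts of the most
#' and least abundant allele at each SNP and the sums run over the SNPs in
#' the window. \eqn{Hp} lies in \eqn{[0, 0.5]}: 0 when every site is
#' monomorphic, 0.5 when major and minor read totals balance. An empty
#' window yields \code{NA} (never 0).
#'
#' @param nMaj,nMin Integer vectors of per-SNP major/minor read counts.
#' @return The Hp value, or \code{NA_real_} for an empty window.
#' @examples
#' hpWindow(c(30, 50), c(10, 10)) # 2*80*20/100^2 = 0.32
#' @export
hpWindow <- function(nMaj, nMin) {
  stopifnot(length(nMaj) == length(nMin))
  if (!length(nMaj)) {
    return(NA_real_)
  }
  s1 <- sum(as.numeric(nMaj))
  s2 <- sum(as.numeric(nMin))
  if (s1 + s2 == 0) {
    return(NA_real_)
  }
  2 * s1 * s2 / (s1 + s2)^2
}

#' Z-transform window Hp values to -ZHp
#'
#' Standardises the Hp values of one pool's retained windows,
#' \eqn{-ZHp = -(Hp - \mu_{Hp}) / \sigma_{Hp}}, so that heterozygosity
#' deficits (candidate sweeps) appear as large positive values. Moments
#' are computed over exactly the windows supplied.
#'
#' @param hp Numeric vector of window Hp values (NAs not allowed).
#' @param sdType \code{"sample"} (denominator n-1, the default) or
#'   \code{"population"} (denominator n).
#' @return A list with \code{negZHp} (vector parallel to \code{hp}),
#'   \code{mu} and \code{sigma}.
#' @examples
#' zhpTransform(c(0.1, 0.2, 0.3))$negZHp # +1, 0, -1
#' @export
zhpTransform <- function(hp, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (anyNA(hp)) stop("undefined Hp values in input")
  n <- length(hp)
  if (n < 2L) stop("need >= 2 windows with defined Hp")
  mu <- mean(hp)
  sigma <- stats::sd(hp)
  if (sdType == "population") sigma <- sigma * sqrt((n - 1) / n)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("zero variance across windows: degenerate scan")
  }
  list(negZHp = -(hp - mu) / sigma, mu = mu, sigma = sigma)
}

#' Windowed pooled-heterozygosity scan of one pool
#'
#' Computes per-window Hp for one pool over the fixed non-overlapping
#' tiling (see \code{\link{makeWindows}}). Sites with zero read depth in
#' the pool are excluded from that pool's scan. \code{zhpScan}
#' additionally Z-transforms the retained windows' Hp values into -ZHp;
#' the moments used are stored in \code{metadata()$moments}.
#'
#' @param x A \linkS4class{PoolCounts} object (normally already filtered
#'   with \code{\link{filterSites}}).
#' @param pool Pool name or index.
#' @param windowSize Window width in bp (default 10000).
#' @param minSnps Minimum SNPs per retained window (default 10).
#' @param sdType Passed to \code{\link{zhpTransform}} (zhpScan only).
#' @return A \code{GRanges} of retained windows with metadata columns
#'   \code{snpCount}, \code{Hp}, \code{pool} (and \code{negZHp} for
#'   \code{zhpScan}); \code{metadata()$n_discarded} counts windows dropped
#'   by the min-SNP rule.
#' @export
hpScan <- function(x, pool, windowSize = 10000L, minSnps = 10L) {
  stopifnot(is(x, "PoolCounts"))
  cm <- .nucMatrix(x, pool)
  nonzero <- rowSums(cm) > 0L
  xs <- x[nonzero]
  cm <- cm[nonzero, , drop = FALSE]
  mm <- .majMin(cm)
  win <- makeWindows(xs, windowSize = windowSize, minSnps = minSnps)
  idx <- mcols(win)$siteIdx
  hp <- vapply(seq_along(win), function(i) {
    j <- idx[[i]]
    hpWindow(mm$nMaj[j], mm$nMin[j])
  }, numeric(1L))
  mcols(win)$siteIdx <- NULL
  mcols(win)$Hp <- hp
  poolName <- if (is.character(pool)) pool else poolNames(x)[pool]
  mcols(win)$pool <- poolName
  win
}

#' @rdname hpScan
#' @export
zhpScan <- function(x, pool, windowSize = 10000L, minSnps = 10L,
                    sdType = c("sample", "population")) {
  win <- hpScan(x, pool, windowSize = windowSize, minSnps = minSnps)
  z <- zhpTransform(mcols(win)$Hp, sdType = match.arg(sdType))
  mcols(win)$negZHp <- z$negZHp
  metadata(win)$moments <- c(mu = z$mu, sigma = z$sigma)
  win
}
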