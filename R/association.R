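#' Chi-square test of genotype-phenotype association
#'
#' Pearson chi-square test (no continuity correction) on a genotype-count
#' table (rows = genotypes, columns = phenotype groups). Genotype rows and
#' group columns whose counts are all zero are dropped before testing —
#' a genotype absent from every group carries no information but would
#' break the statistic's expected counts. Small expected cells (< 5) are
#' reported via the \code{small_cells} element but do not block the test.
#'
#' @param table Non-negative integer matrix of genotype counts with
#'   genotypes as rows and groups as columns (see
#'   \code{\link{readGenotypeTable}}).
#' @return A list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{small_cells} (number of expected counts below 5) and
#'   \code{table} (the pruned table).
#' @examples
#' kitlg <- rbind(GG = c(37, 22, 84), GA = c(77, 3, 0), AA = c(0, 0, 0))
#' colnames(kitlg) <- c("Gray", "White_1", "White_2")
#' chiSquareAssociation(kitlg)$statistic # 102.89
#' @export
chiSquareAssociation <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("genotype counts must be non-negative")
  pruned <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(pruned) < 2L || ncol(pruned) < 2L) {
    stop("pruned genotype table smaller than 2x2: association undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(pruned, correct = FALSE))
  list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = unname(ht$p.value),
    small_cells = sum(ht$expected < 5),
    table = pruned
  )
}

#' Fisher's exact test on allele read depths
#'
#' Two-sided exact hypergeometric test on the 2x2 table of major/minor
#' allele read counts of one SNP in two pools; used to rank SNPs by the
#' strength of allele-frequency differentiation. A zero margin (an allele
#' absent from both pools, or a pool with no reads) makes the table
#' degenerate: p = 1 with a warning.
#'
#' @param depthsA,depthsB Length-2 vectors \code{c(nMaj, nMin)} of allele
#'   read counts in each pool.
#' @return The two-sided p-value.
#' @examples
#' fisherAlleleDepth(c(20, 0), c(0, 20))
#' @export
fisherAlleleDepth <- function(depthsA, depthsB) {
  stopifnot(length(depthsA) == 2L, length(depthsB) == 2L)
  tab <- rbind(depthsA, depthsB)
  if (any(tab < 0)) stop("allele depths must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in allele-depth table: p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Allele frequency from genotype counts
#'
#' Computes the frequency of one allele from the genotype counts of one
#' group: \code{(2 * hom + het) / (2 * N)} where \code{hom} counts
#' individuals homozygous for the allele, \code{het} those carrying one
#' copy, and \code{N} the genotyped individuals.
#'
#' @param counts Named vector of genotype counts; names are two-letter
#'   allele pairs (e.g. \code{GG}, \code{GA}, \code{AA}).
#' @param allele The allele to count (single character).
#' @return The allele frequency in \code{[0, 1]}.
#' @examples
#' afFromGenotypes(c(GG = 37, GA = 77, AA = 0), "A") # 77/228
#' @export
afFromGenotypes <- function(counts, allele) {
  stopifnot(!is.null(names(counts)), nchar(allele) == 1L)
  pairs <- strsplit(names(counts), "")
  if (any(lengths(pairs) != 2L)) {
    stop("genotype labels must be two-letter allele pairs")
  }
  n <- sum(counts)
  if (n == 0) stop("zero genotyped individuals")
  copies <- vapply(pairs, function(p) sum(p == allele), numeric(1L))
  sum(copies * counts) / (2 * n)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among m methods each ranking the same n items, with mid-ranks
#' for ties and the standard tie correction:
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m T}}
#' where S is the sum of squared deviations of the item rank sums from
#' their mean and \eqn{T = \sum (t^3 - t)} over tie groups within each
#' method. W = 1 means identical orderings; with m = 2, exactly reversed
#' orderings give W = 0. Significance uses the chi-square approximation
#' \eqn{\chi^2 = m (n - 1) W} on \eqn{n - 1} degrees of freedom.
#'
#' @param ratings Numeric matrix, n items x m methods (here typically the
#'   Pool-Seq and genotype-based allele-frequency estimates).
#' @return A list with \code{W}, \code{chisq}, \code{df}, \code{p.value}.
#' @examples
#' kendallW(cbind(1:5, c(1.1, 2.2, 2.9, 4.5, 5)))$W # 1
#' @export
kendallW <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  m <- ncol(ratings)
  if (n < 2L || m < 2L) stop("need >= 2 items and >= 2 methods")
  if (anyNA(ratings)) stop("ratings must not contain NA")
  constant <- apply(ratings, 2L, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    stop("constant column (all values tied): W undefined")
  }
  rk <- apply(ratings, 2L, rank) # mid-ranks for ties
  R <- rowSums(rk)
  S <- sum((R - mean(R))^2)
  Tcorr <- sum(apply(rk, 2L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * Tcorr
  if (denom <= 0) stop("degenerate tie structure: W undefined")
  W <- 12 * S / denom
  chisq <- m * (n - 1) * W
  list(
    W = W, chisq = chisq, df = n - 1,
    p.value = stats::pchisq(chisq, n - 1, lower.tail = FALSE)
  )
}

#' Categorise a variant consequence term as loss-of-function
#'
#' Maps Sequence Ontology consequence terms (as emitted by variant-effect
#' annotation) onto the four loss-of-function categories: 1 stop gain/loss,
#' 2 frameshift, 3 essential splice site (donor/acceptor), 4 initiator
#' codon. Any other term (including unknown ones) is \code{NA}: not a LoF
#' class.
#'
#' @param term Character vector of consequence terms.
#' @return Integer vector of categories 1-4, \code{NA} for non-LoF terms.
#' @examples
#' lofCategorize(c("stop_gained", "missense_variant", "splice_acceptor_variant"))
#' @export
lofCategorize <- function(term) {
  map <- c(
    stop_gained = 1L, stop_lost = 1L,
    frameshift_variant = 2L,
    splice_donor_variant = 3L, splice_acceptor_variant = 3L,
    start_lost = 4L, initiator_codon_variant = 4L
  )
  unname(map[term])
}
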