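#' Read a PoPoolation2 sync file
#'
#' Sync is the tab-separated site format used for Pool-Seq allele counts:
#' scaffold, 1-based position, reference base, then one \code{A:T:C:G:N:del}
#' read-count column per pool. Pool identity is positional; names are taken
#' from \code{poolNames} when supplied, otherwise \code{pool1..poolK}.
#'
#' @param path Path to a sync file.
#' @param poolNames Optional character vector naming the pool columns.
#' @return A \linkS4class{PoolCounts} object (zero sites for an empty file).
#' @examples
#' tf <- tempfile(fileext = ".sync")
#' writeLines("sc1\t100\tA\t10:0:5:0:0:0\t15:0:0:0:0:0", tf)
#' readSync(tf, poolNames = c("gray", "white"))
#' @export
readSync <- function(path, poolNames = NULL) {
  if (!file.exists(path)) stop("sync file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    np <- max(length(poolNames), 0L)
    cnt <- array(integer(), c(0L, 6L, np),
      dimnames = list(NULL, SYNC_ALLELES, poolNames)
    )
    return(PoolCounts(character(), integer(), character(), cnt, poolNames))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("sync parse error at line ", lineno[which(nf < 4L)[1L]],
      ": fewer than 4 tab-separated fields")
  }
  if (length(unique(nf)) != 1L) {
    stop("sync structural error at line ",
      lineno[which(nf != nf[1L])[1L]],
      ": inconsistent number of pool columns")
  }
  nPools <- nf[1L] - 3L
  m <- matrix(unlist(fields, use.names = FALSE),
    nrow = length(lines), byrow = TRUE
  )
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos)) {
    stop("sync parse error at line ", lineno[which(is.na(pos))[1L]],
      ": non-integer position")
  }
  counts <- array(NA_integer_, c(length(lines), 6L, nPools),
    dimnames = list(NULL, SYNC_ALLELES, poolNames)
  )
  for (k in seq_len(nPools)) {
    parts <- strsplit(m[, 3L + k], ":", fixed = TRUE)
    bad <- which(lengths(parts) != 6L)
    if (length(bad)) {
      stop("sync parse error at line ", lineno[bad[1L]],
        ": pool column ", k, " does not have 6 ':'-separated counts")
    }
    vals <- suppressWarnings(as.integer(unlist(parts, use.names = FALSE)))
    if (anyNA(vals)) {
      stop("sync parse error at line ",
        lineno[ceiling(which(is.na(vals))[1L] / 6)],
        ": non-integer count in pool column ", k)
    }
    counts[, , k] <- matrix(vals, ncol = 6L, byrow = TRUE)
  }
  PoolCounts(m[, 1L], pos, m[, 3L], counts, poolNames)
}

#' Write a PoolCounts object as a sync file
#'
#' @param x A \linkS4class{PoolCounts} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSync <- function(x, path) {
  stopifnot(is(x, "PoolCounts"))
  if (!length(x)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cols <- vapply(seq_along(poolNames(x)), function(k) {
    cm <- alleleCounts(x, k)
    do.call(paste, c(lapply(seq_len(6L), function(j) cm[, j]), sep = ":"))
  }, character(length(x)))
  dim(cols) <- c(length(x), length(poolNames(x)))
  lines <- do.call(paste, c(
    list(
      as.character(seqnames(x@sites)), start(x@sites),
      as.character(x@sites$ref)
    ),
    lapply(seq_len(ncol(cols)), function(k) cols[, k]),
    sep = "\t"
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-pool allele depths from a VCF
#'
#' Maps the per-sample allele-depth field of a VCF (typically \code{AD},
#' "ref,alt" read counts) onto the nucleotide count map used by the scan
#' statistics. Multiallelic records are split into one biallelic record per
#' ALT allele (sharing the REF depth) and flagged in the \code{split}
#' metadata column. Records where any sample lacks the depth field, and
#' records whose alleles are not single nucleotides, are skipped; the skip
#' count is stored in \code{metadata(siteRanges(x))$n_skipped}.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param depthField FORMAT key holding per-allele read depths
#'   (default \code{"AD"}).
#' @return A \linkS4class{PoolCounts} object with one pool per VCF sample.
#' @export
readAlleleDepthVcf <- function(path, depthField = "AD") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) stop("VCF contains no records")
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!depthField %in% fmt_keys) {
    stop("depth field '", depthField, "' absent from every VCF record")
  }
  ad <- vcfR::extract.gt(v, element = depthField)
  samples <- colnames(ad)
  scaffold <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  out_sc <- character()
  out_pos <- integer()
  out_ref <- character()
  out_split <- logical()
  out_counts <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    depth_str <- ad[i, ]
    if (anyNA(depth_str) || any(depth_str == ".")) {
      n_skipped <- n_skipped + 1L
      next
    }
    dmat <- do.call(rbind, lapply(strsplit(depth_str, ",", fixed = TRUE), as.integer))
    alt_i <- alts[[i]]
    if (ncol(dmat) != length(alt_i) + 1L ||
      !ref[i] %in% NUC_ALLELES ||
      !all(alt_i %in% NUC_ALLELES)) {
      n_skipped <- n_skipped + 1L
      next
    }
    for (a in seq_along(alt_i)) {
      cm <- matrix(0L, length(samples), 6L, dimnames = list(samples, SYNC_ALLELES))
      cm[, ref[i]] <- dmat[, 1L]
      cm[, alt_i[a]] <- dmat[, a + 1L]
      out_sc <- c(out_sc, scaffold[i])
      out_pos <- c(out_pos, pos[i])
      out_ref <- c(out_ref, ref[i])
      out_split <- c(out_split, length(alt_i) > 1L)
      out_counts[[length(out_counts) + 1L]] <- cm
    }
  }
  counts <- array(0L, c(length(out_sc), 6L, length(samples)),
    dimnames = list(NULL, SYNC_ALLELES, samples)
  )
  for (j in seq_along(out_counts)) counts[j, , ] <- t(out_counts[[j]])
  pc <- PoolCounts(out_sc, out_pos, out_ref, counts, samples)
  mcols(pc@sites)$split <- out_split
  metadata(pc@sites)$n_skipped <- n_skipped
  pc
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 input keeps only \code{gene} features; BED input (0-based
#' half-open) is converted to the internal 1-based inclusive convention by
#' \pkg{rtracklayer}. Gene identifiers come from the GFF3 \code{ID} /
#' \code{gene_id} / \code{Name} attribute or the BED name column.
#'
#' @param path Path to a \code{.gff}/\code{.gff3} or \code{.bed} file.
#' @param format \code{"auto"} (from extension), \code{"gff3"} or
#'   \code{"bed"}.
#' @return A \code{GRanges} with a \code{gene_id} metadata column.
#' @export
readGenes <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    is_gene <- !is.na(gr$type) & as.character(gr$type) == "gene"
    gr <- gr[is_gene]
    if (!length(gr)) {
      warning("no 'gene' features found in ", path)
    }
    id <- gr$ID
    if (is.null(id)) id <- gr$gene_id
    if (is.null(id)) id <- gr$Name
    if (is.null(id)) id <- paste0("gene", seq_along(gr))
    id[is.na(id)] <- paste0("gene", which(is.na(id)))
    gene_id <- as.character(id)
  } else {
    gene_id <- if (!is.null(gr$name)) as.character(gr$name) else paste0("gene", seq_along(gr))
  }
  mcols(gr) <- DataFrame(gene_id = gene_id)
  if (any(end(gr) < start(gr))) stop("gene interval with end < start")
  gr
}

#' Write windows to a BED file
#'
#' Writes window statistics as BED4 (0-based half-open): scaffold, start,
#' end and a name of the form \code{<label>=<value>} with the statistic at
#' fixed 6-decimal formatting. Output is sorted by scaffold (lexicographic)
#' then start, so identical inputs give byte-identical files.
#'
#' @param windows A \code{GRanges} of windows.
#' @param path Output path.
#' @param column Metadata column holding the statistic (default the first
#'   numeric column).
#' @param label Statistic label in the name field; defaults to
#'   \code{column}.
#' @return \code{path}, invisibly.
#' @export
writeWindowsBed <- function(windows, path, column = NULL, label = NULL) {
  if (!length(windows)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  mc <- mcols(windows)
  if (is.null(column)) {
    numcols <- names(mc)[vapply(mc, is.numeric, logical(1L))]
    numcols <- setdiff(numcols, "snpCount")
    if (!length(numcols)) stop("no numeric statistic column to write")
    column <- numcols[1L]
  }
  if (is.null(label)) label <- column
  sc <- as.character(seqnames(windows))
  o <- order(sc, start(windows), method = "radix")
  lines <- sprintf(
    "%s\t%d\t%d\t%s=%.6f",
    sc[o], start(windows)[o] - 1L, end(windows)[o],
    label, as.numeric(mc[[column]])[o]
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype count table
#'
#' Expects a TSV with the genotype label in the first column and one count
#' column per phenotype group; the header row (optionally starting with
#' \code{#}) carries the group names.
#'
#' @param path Path to the TSV.
#' @return An integer matrix, rows = genotypes, columns = groups.
#' @export
readGenotypeTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genotype table needs a header and >= 1 row")
  lines[1L] <- sub("^#\\s*", "", lines[1L])
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1L]])
  if (any(m < 0, na.rm = TRUE) || anyNA(m)) {
    stop("genotype counts must be non-negative integers")
  }
  m
}

#' Write a genotype count table as TSV
#'
#' @param table Integer matrix, rows = genotypes, columns = groups.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTable <- function(table, path) {
  lines <- c(
    paste(c("#genotype", colnames(table)), collapse = "\t"),
    vapply(seq_len(nrow(table)), function(i) {
      paste(c(rownames(table)[i], table[i, ]), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}
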