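.writeTsv <- function(df, path, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1L))
  int <- vapply(df, is.integer, logical(1L))
  for (j in which(num & !int)) df[[j]] <- sprintf(paste0("%.", digits, "f"), df[[j]])
  lines <- c(
    paste0("#", paste(names(df), collapse = "\t")),
    if (nrow(df)) {
      do.call(paste, c(lapply(df, as.character), sep = "\t"))
    } else {
      character()
    }
  )
  writeLines(lines, path)
  invisible(path)
}

.windowsToDf <- function(win, valueCol) {
  data.frame(
    scaffold = as.character(seqnames(win)),
    start = start(win), end = end(win),
    n_snps = mcols(win)$snpCount,
    value = as.numeric(mcols(win)[[valueCol]]),
    stringsAsFactors = FALSE
  )
}

#' Read a flat key=value run configuration
#'
#' Parses a plain-text configuration of \code{key = value} lines
#' (\code{#} comments allowed) into the list consumed by
#' \code{\link{runSweepPipeline}}. Recognised keys: \code{sync},
#' \code{genes}, \code{out_dir}, \code{pool_names},
#' \code{haploid_sizes} (comma-separated, parallel to pool_names),
#' \code{gray_pool}, \code{white_pools} (comma-separated),
#' \code{min_depth}, \code{max_depth}, \code{min_maf}, \code{min_quality},
#' \code{indel_exclusion_bp}, \code{window_size}, \code{min_snps},
#' \code{top_fraction}, \code{flank_bp}, \code{seed}. Defaults are the
#' standard scan parameters (10-kb windows, min 10 SNPs, top 3\%, 10-kb
#' flanks, depth 10-100, MAF 0.05).
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("config parse error at: ", lines[bad[1L]])
  cfg <- stats::setNames(
    lapply(kv, function(x) trimws(x[3L])),
    vapply(kv, function(x) trimws(x[2L]), character(1L))
  )
  split_csv <- function(x) trimws(strsplit(x, ",")[[1L]])
  out <- list(
    sync = cfg$sync,
    genes = cfg$genes,
    out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
    pool_names = if (is.null(cfg$pool_names)) NULL else split_csv(cfg$pool_names),
    haploid_sizes = if (is.null(cfg$haploid_sizes)) NULL else as.numeric(split_csv(cfg$haploid_sizes)),
    gray_pool = cfg$gray_pool,
    white_pools = if (is.null(cfg$white_pools)) NULL else split_csv(cfg$white_pools),
    min_depth = if (is.null(cfg$min_depth)) 10L else as.integer(cfg$min_depth),
    max_depth = if (is.null(cfg$max_depth)) 100L else as.integer(cfg$max_depth),
    min_maf = if (is.null(cfg$min_maf)) 0.05 else as.numeric(cfg$min_maf),
    min_quality = if (is.null(cfg$min_quality)) 20 else as.numeric(cfg$min_quality),
    indel_exclusion_bp = if (is.null(cfg$indel_exclusion_bp)) 15L else as.integer(cfg$indel_exclusion_bp),
    window_size = if (is.null(cfg$window_size)) 10000L else as.integer(cfg$window_size),
    min_snps = if (is.null(cfg$min_snps)) 10L else as.integer(cfg$min_snps),
    top_fraction = if (is.null(cfg$top_fraction)) 0.03 else as.numeric(cfg$top_fraction),
    flank_bp = if (is.null(cfg$flank_bp)) 10000L else as.integer(cfg$flank_bp),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  )
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

#' Run the full sweep-detection pipeline
#'
#' Executes the complete genome scan on a sync dataset: site filtering,
#' per-white-pool Hp / -ZHp scans, per-(gray, white) F_ST scans, per-scan
#' top-quantile thresholds, the two intersections (both F_ST comparisons;
#' both -ZHp pools), their final overlap, and gene overlap with flanks.
#' All outputs are written to \code{out_dir} together with a manifest
#' listing each file with its md5 checksum; identical configuration and
#' inputs give an identical manifest.
#'
#' @param config A configuration list (see \code{\link{readRunConfig}}),
#'   or a path to a configuration file.
#' @return Invisibly, a list with \code{finalCalls}
#'   (\linkS4class{SweepCallSet}), \code{geneHits}, \code{tally},
#'   \code{thresholds}, \code{manifest} (data.frame of file, md5) and
#'   \code{outputs} (named paths).
#' @export
runSweepPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$sync)) stop("config must name a 'sync' input")
  if (is.null(config$gray_pool) || length(config$white_pools) < 2L) {
    stop("config must name gray_pool and two white_pools")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  pc <- .stage("read", readSync(config$sync, poolNames = config$pool_names))
  if (is.null(config$haploid_sizes)) {
    stop("config must give haploid_sizes (chromosomes per pool)")
  }
  sizes <- stats::setNames(config$haploid_sizes, poolNames(pc))

  params <- SiteFilterParams(
    minDepth = config$min_depth, maxDepth = config$max_depth,
    minMAF = config$min_maf, minQuality = config$min_quality,
    indelExclusionBp = config$indel_exclusion_bp
  )
  flt <- .stage("filter", filterSites(pc, params))

  gray <- config$gray_pool
  whites <- config$white_pools
  ws <- config$window_size
  ms <- config$min_snps
  tf <- config$top_fraction

  zhpWins <- .stage("zhp", lapply(whites, function(p) {
    zhpScan(flt$counts, p, windowSize = ws, minSnps = ms)
  }))
  fstWins <- .stage("fst", lapply(whites, function(p) {
    fstScan(flt$counts, gray, p,
      poolSizes = c(sizes[[gray]], sizes[[p]]),
      windowSize = ws, minSnps = ms
    )
  }))

  zhpSel <- .stage("thresholds", lapply(zhpWins, selectTopWindows,
    column = "negZHp", topFraction = tf
  ))
  fstSel <- .stage("thresholds", lapply(fstWins, selectTopWindows,
    column = "Fst", topFraction = tf
  ))
  th <- c(
    stats::setNames(
      vapply(fstSel, `[[`, numeric(1L), "cutoff"),
      paste0("Fst_", gray, "_vs_", whites)
    ),
    stats::setNames(
      vapply(zhpSel, `[[`, numeric(1L), "cutoff"),
      paste0("negZHp_", whites)
    )
  )

  fstInt <- .stage("intersect", SweepCallSet(
    "FST_INTERSECT",
    suppressWarnings(intersectScans(fstSel[[1L]]$windows, fstSel[[2L]]$windows)),
    th[seq_len(2L)]
  ))
  zhpInt <- .stage("intersect", SweepCallSet(
    "ZHP_INTERSECT",
    suppressWarnings(intersectScans(zhpSel[[1L]]$windows, zhpSel[[2L]]$windows)),
    th[3:4]
  ))
  final <- .stage("final", finalOverlap(fstInt, zhpInt))

  genes <- if (!is.null(config$genes) && nzchar(config$genes)) {
    .stage("genes", suppressWarnings(readGenes(config$genes)))
  } else {
    GRanges()
  }
  hits <- .stage("genes", overlapGenes(final, genes, flankBp = config$flank_bp))

  out <- c(
    filter_tally = "filter_tally.tsv",
    thresholds = "thresholds.tsv",
    final_regions = "final_regions.bed",
    gene_hits = "gene_hits.tsv"
  )
  scanFiles <- c(
    stats::setNames(
      sprintf("windows_zhp_%s.tsv", whites),
      paste0("windows_zhp_", whites)
    ),
    stats::setNames(
      sprintf("windows_fst_%s_vs_%s.tsv", gray, whites),
      paste0("windows_fst_", whites)
    )
  )
  out <- c(out, scanFiles)
  paths <- stats::setNames(file.path(config$out_dir, out), names(out))

  .writeTsv(
    data.frame(reason = names(flt$tally), count = as.integer(flt$tally)),
    paths[["filter_tally"]]
  )
  .writeTsv(
    data.frame(scan = names(th), cutoff = as.numeric(th)),
    paths[["thresholds"]]
  )
  for (i in seq_along(whites)) {
    .writeTsv(
      .windowsToDf(zhpWins[[i]], "negZHp"),
      paths[[paste0("windows_zhp_", whites[i])]]
    )
    .writeTsv(
      .windowsToDf(fstWins[[i]], "Fst"),
      paths[[paste0("windows_fst_", whites[i])]]
    )
  }
  reg <- sweepRegions(final)
  writeLines(
    if (length(reg)) {
      sprintf(
        "%s\t%d\t%d\tsweep%03d", as.character(seqnames(reg)),
        start(reg) - 1L, end(reg), seq_along(reg)
      )
    } else {
      character()
    },
    paths[["final_regions"]]
  )
  .writeTsv(hits, paths[["gene_hits"]])

  manifest <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  .writeTsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  invisible(list(
    finalCalls = final, fstCalls = fstInt, zhpCalls = zhpInt,
    geneHits = hits, tally = flt$tally, thresholds = th,
    manifest = manifest, outputs = paths
  ))
}
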