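test_that("window assignment boundary follows the ceiling convention", {
  pc <- make_pc(
    rep("sc1", 22), c(sort(sample(2:9999, 10)), 10000L, 10001L, sort(sample(10002:20000, 10))),
    list(matrix(rpois(88, 20), 22, 4))
  )
  win <- makeWindows(pc, windowSize = 10000, minSnps = 10)
  expect_equal(start(win), c(1L, 10001L))
  expect_equal(unname(mcols(win)$snpCount), c(11L, 11L)) # 10000 -> win 1, 10001 -> win 2
})

test_that("windows below the min-SNP count are discarded", {
  pos <- c(sort(sample(1:10000, 9)), sort(sample(10001:20000, 10)))
  win <- makeWindows(rep("sc1", 19), pos, windowSize = 10000, minSnps = 10)
  expect_equal(length(win), 1L)
  expect_equal(start(win), 10001L)
  expect_equal(S4Vectors::metadata(win)$n_discarded, 1L)
})

test_that("window membership matches a direct per-site assignment", {
  set.seed(14)
  pos <- sort(sample(1:30000, 25))
  win <- makeWindows(rep("sc1", 25), pos, windowSize = 10000, minSnps = 10)
  direct <- table(ceiling(pos / 10000))
  keep <- direct[direct >= 10]
  expect_equal(length(win), length(keep))
  expect_equal(unname(mcols(win)$snpCount), unname(as.integer(keep)))
  expect_equal(start(win), (as.integer(names(keep)) - 1L) * 10000L + 1L)
})

test_that("trailing partial windows are clipped at the scaffold end", {
  win <- makeWindows(rep("sc1", 12), sort(sample(20001:25000, 12)),
    windowSize = 10000, minSnps = 10,
    seqlengths = c(sc1 = 25000)
  )
  expect_equal(start(win), 20001L)
  expect_equal(end(win), 25000L)
})

test_that("top-quantile cutoff uses the 'higher' rule with inclusive ties", {
  th <- topQuantileThreshold(1:100, 0.03)
  expect_equal(th$cutoff, 98)
  expect_equal(which(th$selected), 98:100)

  expect_warning(one <- topQuantileThreshold(5, 0.03), "single")
  expect_true(one$selected)

  vals <- c(1, 2, 3, 98, 98, 98, rep(50, 94))
  th2 <- topQuantileThreshold(vals, 0.03)
  expect_equal(sum(th2$selected), 3L) # the tied 98s all selected

  expect_error(topQuantileThreshold(rep(7, 10), 0.03), "identical")
})

test_that("selection size is bounded for random inputs", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(50:2000, 1)
    f <- runif(1, 0.01, 0.2)
    v <- rnorm(n) # continuous: ties almost surely absent
    th <- topQuantileThreshold(v, f)
    k <- sum(th$selected)
    expect_gte(k, floor(n * f) - 1)
    expect_lte(k, ceiling(n * f) + 1)
    expect_true(all(v[!th$selected] < min(v[th$selected])))
  }
})

test_that("scan intersection matches exactly and is commutative", {
  w <- GRanges("sc1", IRanges(c(1, 10001, 20001), width = 10000))
  mcols(w)$Fst <- c(0.5, 0.6, 0.7)
  a <- w[1:2]
  b <- w[2:3]
  ab <- intersectScans(a, b)
  expect_equal(start(ab), 10001L)
  expect_equal(mcols(ab)$Fst, 0.6)
  expect_equal(mcols(ab)$Fst.1, 0.6) # both scans' values carried

  ba <- intersectScans(b, a)
  expect_identical(granges(ab), granges(ba))
  expect_identical(granges(intersectScans(a, a)), granges(a)) # idempotent

  expect_warning(none <- intersectScans(a, w[3]), "empty")
  expect_equal(length(none), 0L)

  shifted <- GRanges("sc1", IRanges(5001, 15000), Fst = 1)
  expect_error(intersectScans(a, shifted), "incompatible")
})

test_that("final overlap is contained in both inputs and merges adjacency", {
  w <- GRanges("sc1", IRanges(c(1, 10001, 20001, 40001), width = 10000))
  mcols(w)$negZHp <- 1:4
  fstIn <- SweepCallSet("FST_INTERSECT", w[c(1, 2, 4)], c(f = 0.1))
  zhpIn <- SweepCallSet("ZHP_INTERSECT", w[1:3], c(z = 2))
  fin <- finalOverlap(fstIn, zhpIn)
  expect_equal(sweepStep(fin), "FINAL_OVERLAP")
  expect_equal(length(sweepWindows(fin)), 2L)
  # containment in both inputs
  expect_true(all(.windowKeyTest(sweepWindows(fin)) %in% .windowKeyTest(sweepWindows(fstIn))))
  expect_true(all(.windowKeyTest(sweepWindows(fin)) %in% .windowKeyTest(sweepWindows(zhpIn))))
  # adjacent windows [1,10000], [10001,20000] merge into one region
  expect_equal(length(sweepRegions(fin)), 1L)
  expect_equal(start(sweepRegions(fin)), 1L)
  expect_equal(end(sweepRegions(fin)), 20000L)
  expect_equal(thresholds(fin), c(f = 0.1, z = 2))

  emptyIn <- SweepCallSet("FST_INTERSECT", w[integer()])
  finEmpty <- finalOverlap(emptyIn, zhpIn)
  expect_equal(length(sweepWindows(finEmpty)), 0L)
})

test_that("gene overlap honours inclusive flanks and is monotone in flank", {
  genes <- GRanges("sc1", IRanges(30000, 40000), gene_id = "geneA")
  hitReg <- GRanges("sc1", IRanges(15000, 21000))
  # region end 21000 >= 30000 - 10000: hit
  expect_equal(nrow(overlapGenes(hitReg, genes, flankBp = 10000)), 1L)
  # region [5000, 9000] misses even with the flank
  expect_equal(nrow(overlapGenes(GRanges("sc1", IRanges(5000, 9000)), genes, 10000)), 0L)
  # gene entirely inside one region
  span <- overlapGenes(GRanges("sc1", IRanges(20000, 50000)), genes, 10000)
  expect_equal(span$n_regions, 1L)

  set.seed(2)
  regs <- GRanges("sc1", IRanges(sort(sample.int(2e5, 10)) * 10 + 1, width = 8000))
  genes2 <- GRanges("sc1", IRanges(sort(sample.int(2e6, 30)), width = 5000),
    gene_id = paste0("g", 1:30)
  )
  hit0 <- overlapGenes(regs, genes2, flankBp = 0)
  hit10 <- overlapGenes(regs, genes2, flankBp = 10000)
  expect_true(all(hit0$gene_id %in% hit10$gene_id))
})
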