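test_that("sync lines map onto per-pool allele counts", {
  tf <- withr::local_tempfile(fileext = ".sync")
  writeLines("sc1\t100\tA\t10:0:5:0:0:0\t15:0:0:0:0:0", tf)
  pc <- readSync(tf)
  expect_equal(length(pc), 1L)
  expect_equal(poolNames(pc), c("pool1", "pool2"))
  expect_equal(unname(alleleCounts(pc, 1)[, "A"]), 10L)
  expect_equal(unname(alleleCounts(pc, 1)[, "C"]), 5L)
  expect_equal(sum(alleleCounts(pc, 2)), 15L)
  expect_equal(unname(alleleCounts(pc, 2)[, "A"]), 15L)
  expect_equal(start(siteRanges(pc)), 100L)
})

test_that("empty sync files give an empty record set without error", {
  tf <- withr::local_tempfile(fileext = ".sync")
  writeLines(character(), tf)
  pc <- readSync(tf)
  expect_s4_class(pc, "PoolCounts")
  expect_equal(length(pc), 0L)
})

test_that("malformed sync columns raise parse errors naming the line", {
  tf <- withr::local_tempfile(fileext = ".sync")
  writeLines(c(
    "sc1\t100\tA\t10:0:5:0:0:0",
    "sc1\t200\tA\t10:0:5"
  ), tf)
  expect_error(readSync(tf), "line 2")

  writeLines(c(
    "sc1\t100\tA\t10:0:5:0:0:0",
    "sc1\t200\tA\t10:0:x:0:0:0"
  ), tf)
  expect_error(readSync(tf), "line 2")

  writeLines(c(
    "sc1\t100\tA\t10:0:5:0:0:0\t1:2:3:4:5:6",
    "sc1\t200\tA\t10:0:5:0:0:0"
  ), tf)
  expect_error(readSync(tf), "inconsistent")
})

test_that("sync write/read round trip reproduces counts exactly", {
  set.seed(7)
  n <- 50
  arr <- array(
    rpois(n * 6 * 3, 8), c(n, 6, 3),
    dimnames = list(NULL, syncAlleles(), NULL)
  )
  storage.mode(arr) <- "integer"
  pc <- PoolCounts(
    rep(c("sc2", "sc1"), c(20, 30)),
    c(sort(sample.int(1e5, 20)), sort(sample.int(1e5, 30))),
    sample(c("A", "C", "G", "T"), n, TRUE), arr,
    poolNames = c("gray", "white1", "white2")
  )
  tf <- withr::local_tempfile(fileext = ".sync")
  writeSync(pc, tf)
  back <- readSync(tf, poolNames = poolNames(pc))
  expect_identical(unname(alleleCounts(back)), unname(alleleCounts(pc)))
  expect_equal(start(siteRanges(back)), start(siteRanges(pc)))
  expect_equal(
    as.character(seqnames(siteRanges(back))),
    as.character(seqnames(siteRanges(pc)))
  )
})

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tgray\twhite"
)

test_that("VCF allele depths map onto the nucleotide count table", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    vcf_header,
    "sc1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:30,14\t1/1:2,40"
  ), tf)
  pc <- readAlleleDepthVcf(tf)
  expect_equal(length(pc), 1L)
  expect_equal(unname(alleleCounts(pc, "gray")[, "A"]), 30L)
  expect_equal(unname(alleleCounts(pc, "gray")[, "G"]), 14L)
  expect_equal(unname(alleleCounts(pc, "white")[, "G"]), 40L)
})

test_that("multiallelic VCF records split into flagged biallelic sites", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    vcf_header,
    "sc1\t100\t.\tA\tG,T\t50\tPASS\t.\tGT:AD\t0/1:30,10,4\t1/1:2,40,1"
  ), tf)
  pc <- readAlleleDepthVcf(tf)
  expect_equal(length(pc), 2L)
  expect_true(all(siteRanges(pc)$split))
  expect_equal(start(siteRanges(pc)), c(100L, 100L))
  expect_equal(unname(alleleCounts(pc, "gray")[1, "G"]), 10L)
  expect_equal(unname(alleleCounts(pc, "gray")[2, "T"]), 4L)
  # REF depth shared by both split records
  expect_equal(unname(unname(alleleCounts(pc, "gray")[, "A"])), c(30L, 30L))
})

test_that("records lacking the depth field are skipped and counted", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    vcf_header,
    "sc1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:30,14\t1/1:.\t",
    "sc1\t200\t.\tC\tT\t50\tPASS\t.\tGT:AD\t0/1:9,9\t0/1:8,8"
  ), tf)
  pc <- readAlleleDepthVcf(tf)
  expect_equal(length(pc), 1L)
  expect_equal(S4Vectors::metadata(siteRanges(pc))$n_skipped, 1L)
  expect_error(readAlleleDepthVcf(tf, depthField = "DPX"), "absent")
})

test_that("BED gene intervals convert to 1-based inclusive coordinates", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("sc1\t999\t2000\tgeneX\t0\t+", tf)
  g <- readGenes(tf)
  expect_equal(start(g), 1000L)
  expect_equal(end(g), 2000L)
  expect_equal(g$gene_id, "geneX")
})

test_that("GFF3 input keeps gene features and warns when none exist", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=geneA",
    "sc1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=tx1;Parent=geneA"
  ), tf)
  g <- readGenes(tf)
  expect_equal(length(g), 1L)
  expect_equal(start(g), 1000L)
  expect_equal(end(g), 2000L)
  expect_equal(g$gene_id, "geneA")

  writeLines(c(
    "##gff-version 3",
    "sc1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=tx1"
  ), tf)
  expect_warning(g2 <- readGenes(tf), "no 'gene' features")
  expect_equal(length(g2), 0L)
})

test_that("window BED output is 0-based, sorted and fixed-format", {
  win <- GRanges(
    c("sc2", "sc1", "sc1"),
    IRanges(c(1, 10001, 1), c(10000, 20000, 10000))
  )
  mcols(win)$Hp <- c(0.1, 0.3, 0.25)
  tf <- withr::local_tempfile(fileext = ".bed")
  writeWindowsBed(win, tf, column = "Hp")
  lines <- readLines(tf)
  expect_equal(lines[1], "sc1\t0\t10000\tHp=0.250000")
  expect_equal(lines[2], "sc1\t10000\t20000\tHp=0.300000")
  expect_equal(lines[3], "sc2\t0\t10000\tHp=0.100000")

  writeWindowsBed(GRanges(), tf)
  expect_length(readLines(tf), 0L)
})

test_that("BED round trip through gene reader inverts the conversion", {
  win <- GRanges("sc1", IRanges(c(1, 10001), c(10000, 20000)), value = c(1, 2))
  tf <- withr::local_tempfile(fileext = ".bed")
  writeWindowsBed(win, tf, column = "value")
  back <- readGenes(tf)
  expect_equal(start(back), start(win))
  expect_equal(end(back), end(win))
})

test_that("genotype tables survive a TSV round trip", {
  tab <- verified_genotype_tables()$KITLG
  storage.mode(tab) <- "integer"
  colnames(tab) <- c("Gray", "White_1", "White_2")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(tab, tf)
  back <- readGenotypeTable(tf)
  expect_identical(back, tab)
})
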