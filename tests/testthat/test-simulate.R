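test_that("identical seeds give byte-identical datasets", {
  cfg <- sweep_sim_config(99, nScaffolds = 1, scaffoldLength = 1e5,
    sweeps = data.frame(
      scaffold = "scaffold01", start = 40001L, end = 60000L,
      target_pools = "white1,white2", derived_freq = 0.98
    )
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulation(simulatePoolCounts(cfg), d1)
  writeSimulation(simulatePoolCounts(cfg), d2)
  for (f in c("pools.sync", "truth.tsv", "sweeps.bed")) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f)))
    )
  }
  # different seed -> different data
  cfg2 <- sweep_sim_config(100,
    nScaffolds = 1, scaffoldLength = 1e5,
    sweeps = data.frame(
      scaffold = "scaffold01", start = 40001L, end = 60000L,
      target_pools = "white1,white2", derived_freq = 0.98
    )
  )
  d3 <- withr::local_tempdir()
  writeSimulation(simulatePoolCounts(cfg2), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "pools.sync"))),
    unname(tools::md5sum(file.path(d3, "pools.sync")))
  ))
})

test_that("complete sweeps without sequencing error force Hp = 0 windows", {
  cfg <- SimulationConfig(
    nScaffolds = 1, scaffoldLength = 1e5, snpDensity = 0.005,
    sweepRegions = data.frame(
      scaffold = "scaffold01", start = 20001L, end = 60000L,
      target_pools = "white1", derived_freq = 1.0
    ),
    errorRate = 0, driftSd = 0, seed = 12
  )
  sim <- simulatePoolCounts(cfg)
  inReg <- start(siteRanges(sim$counts)) >= 20001 &
    start(siteRanges(sim$counts)) <= 60000
  cm <- alleleCounts(sim$counts, "white1")[inReg, c("A", "C", "G", "T")]
  # every site monomorphic for the derived allele
  expect_true(all(rowSums(cm > 0) == 1))
  win <- hpScan(sim$counts, "white1")
  inWin <- start(win) >= 20001 & end(win) <= 60000
  expect_true(all(mcols(win)$Hp[inWin] == 0))
})

test_that("realised depth and allele frequencies track the truth", {
  cfg <- SimulationConfig(
    nScaffolds = 1, scaffoldLength = 5e6, snpDensity = 0.002,
    seed = 5
  )
  sim <- simulatePoolCounts(cfg) # ~1e4 sites
  d <- depths(sim$counts)
  expect_gt(nrow(d), 9000)
  for (k in 1:3) {
    expect_lt(abs(mean(d[, k]) - 44) / 44, 0.05)
  }

  # deep sequencing: empirical derived-allele frequency converges to truth
  deep <- SimulationConfig(
    nScaffolds = 1, scaffoldLength = 5e4, snpDensity = 0.002,
    pools = data.frame(
      pool_id = "p1", n_diploids = 100L, mean_depth = 10000
    ),
    errorRate = 0, seed = 6
  )
  dsim <- simulatePoolCounts(deep)
  derived <- dsim$truth$derived
  cm <- alleleCounts(dsim$counts, 1)[, c("A", "C", "G", "T")]
  emp <- cm[cbind(seq_len(nrow(cm)), match(derived, c("A", "C", "G", "T")))] /
    rowSums(cm)
  expect_lt(max(abs(emp - dsim$truth$freq_p1)), 0.02)
})

test_that("no-sweep simulations have near-null F_ST tails", {
  cfg <- SimulationConfig(nScaffolds = 1, scaffoldLength = 1e6, seed = 40)
  sim <- simulatePoolCounts(cfg)
  flt <- filterSites(sim$counts)
  f <- fstScan(flt$counts, "gray", "white2", c(234, 174))
  expect_lt(abs(mean(mcols(f)$Fst)), 0.02) # centred near zero
  # the 3% tail of the observed distribution is small in absolute terms
  th <- topQuantileThreshold(mcols(f)$Fst, 0.03)
  expect_lt(th$cutoff, 0.05)
})

test_that("simulated genotype tables are multinomial and reproducible", {
  p <- cbind(Gray = c(0.3, 0.6, 0.1), White = c(0.9, 0.1, 0))
  rownames(p) <- c("GG", "GA", "AA")
  t1 <- simulateGenotypeTable(c(Gray = 100, White = 80), p, seed = 3)
  t2 <- simulateGenotypeTable(c(Gray = 100, White = 80), p, seed = 3)
  expect_identical(t1, t2)
  expect_equal(unname(colSums(t1)), c(100L, 80L))
  expect_equal(rownames(t1), c("GG", "GA", "AA"))

  expect_error(
    simulateGenotypeTable(c(10, 10), cbind(c(0.5, 0.4), c(0.5, 0.5))),
    "sum to 1"
  )
  expect_error(
    simulateGenotypeTable(c(-1, 10), cbind(c(1, 0), c(1, 0))),
    "non-negative"
  )

  # a degenerate design (one genotype everywhere) trips the association
  # error path downstream
  pd <- cbind(A = c(1, 0), B = c(1, 0))
  rownames(pd) <- c("GG", "GA")
  td <- simulateGenotypeTable(c(A = 50, B = 50), pd, seed = 8)
  expect_error(chiSquareAssociation(td), "2x2")
})
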