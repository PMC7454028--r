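test_that("stochastic growth rate is the geometric mean of size ratios", {
  expect_equal(stochasticGrowthRate(makeRecords(rep(1000L, 5))), 1.0)
  expect_equal(stochasticGrowthRate(makeRecords(c(10L, 20L, 40L, 80L))), 2.0)
  expect_equal(stochasticGrowthRate(makeRecords(c(1000L, 500L, 1000L))), 1.0)
  ## zero-size pairs are excluded
  expect_equal(stochasticGrowthRate(makeRecords(c(100L, 0L, 0L, 100L, 200L))),
               2.0)
  expect_true(is.na(stochasticGrowthRate(makeRecords(c(0L, 0L, 0L)))))
  expect_error(stochasticGrowthRate(makeRecords(100L)), "2 generations")
})

test_that("extinction and recolonization rates count per-generation events", {
  expect_equal(unname(extinctionRecolonizationRates(makeRecords(rep(10L, 4)))),
               c(0, 0))
  expect_equal(
    unname(extinctionRecolonizationRates(makeRecords(c(5L, 0L, 5L, 0L)))),
    c(0.5, 0.25))
  expect_equal(
    unname(extinctionRecolonizationRates(makeRecords(rep(0L, 10)))),
    c(1, 0))
})

test_that("zero migration rate makes the event probability irrelevant", {
  spec <- ScenarioSpec(nReplicates = 3L,
                       config = SimulationConfig(nGenerations = 10L, n0 = 50L,
                                                 nLoci = 10L),
                       baseSeed = 5L, nPerm = 0L)
  s0 <- runScenario(0, 0, spec)
  s1 <- runScenario(0, 1, spec)
  expect_equal(s0[, setdiff(names(s0), "pEvent")],
               s1[, setdiff(names(s1), "pEvent")])
})

test_that("the grid driver is deterministic and shaped by its spec", {
  spec <- ScenarioSpec(mGrid = c(0, 0.5), pEventGrid = c(0.2, 1),
                       nReplicates = 2L,
                       config = SimulationConfig(nGenerations = 8L, n0 = 40L,
                                                 nLoci = 10L),
                       baseSeed = 9L, nPerm = 0L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- runGrid(spec, outFile = f1)
  g2 <- runGrid(spec, outFile = f2)
  expect_equal(nrow(g1), 4L)
  expect_true(all(c("meanFst", "meanHs", "meanCentroidDistance",
                    "extinctionRate") %in% names(g1)))
  expect_identical(g1, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(is.finite(g1$meanDemeSize)))
})

test_that("the significance fraction is high without migration and drops
           with strong mixing", {
  cfg <- SimulationConfig(nGenerations = 30L, n0 = 150L, nLoci = 40L)
  spec <- ScenarioSpec(nReplicates = 10L, config = cfg, baseSeed = 77L,
                       nPerm = 100L)
  s0 <- runScenario(0, 0, spec)
  sM <- runScenario(0.5, 1, spec)
  expect_gte(s0$fracSignificant, 0.9)
  expect_lt(sM$fracSignificant, s0$fracSignificant)
  expect_lt(sM$meanFst, s0$meanFst)
})

test_that("the U-shape detector answers constructed cases correctly", {
  set.seed(30)
  r <- rep(c(0, 0.2, 0.45, 0.7, 0.9), each = 12)
  u <- (r - 0.45)^2 + rnorm(length(r), 0, 0.01)
  res <- migrationDistanceCurve(r, u)
  expect_true(res$uShape)
  expect_lt(abs(res$vertex - 0.45), 0.1)
  expect_equal(nrow(res$curve), 5L)
  ## monotone decreasing: no U-shape
  mono <- 1 - r + rnorm(length(r), 0, 0.01)
  expect_false(migrationDistanceCurve(r, mono)$uShape)
  ## constant input: no verdict, no error
  expect_false(migrationDistanceCurve(r, rep(1, length(r)))$uShape)
  expect_error(migrationDistanceCurve(c(0, 0, 1, 1), 1:4), "3 distinct")
})
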