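test_that("AMOVA components match the brute-force oracle on toy data", {
  set.seed(10)
  cases <- list(
    list(nGroups = 2, nPerGroup = 4, nLoci = 1, nAlleles = 2, missingRate = 0),
    list(nGroups = 2, nPerGroup = 4, nLoci = 3, nAlleles = 3, missingRate = 0),
    list(nGroups = 3, nPerGroup = 5, nLoci = 2, nAlleles = 4, missingRate = 0),
    list(nGroups = 2, nPerGroup = 6, nLoci = 4, nAlleles = 3,
         missingRate = 0.15))
  for (cs in cases) {
    gg <- do.call(randomToyGenotypes, cs)
    got <- amovaFst(gg, "pop", nPerm = 0)
    oracle <- bruteAmovaFst(gg@allele1, gg@allele2, groupData(gg)$pop)
    expect_equal(fstValue(got), oracle$fst, tolerance = 1e-12)
    expect_equal(got@components$sigma2, unname(oracle$components),
                 tolerance = 1e-12)
  }
})

test_that("FST hits the boundary cases exactly", {
  gg <- fixedDifferencePair()
  expect_equal(fstValue(amovaFst(gg, "pop", nPerm = 0)), 1)
  ## one deme duplicated as two groups: no between-group variance
  set.seed(11)
  one <- randomToyGenotypes(nGroups = 1, nPerGroup = 8, nLoci = 5,
                            nAlleles = 4)
  dup <- GroupedGenotypes(rbind(one@allele1, one@allele1),
                          rbind(one@allele2, one@allele2),
                          data.frame(pop = rep(c("a", "b"), each = 8)))
  expect_lte(fstValue(amovaFst(dup, "pop", nPerm = 0)), 0)
  ## monomorphic data: flagged NaN
  mono <- GroupedGenotypes(matrix(5L, 6, 2), matrix(5L, 6, 2),
                           data.frame(pop = rep(c("a", "b"), each = 3)))
  expect_warning(res <- amovaFst(mono, "pop", nPerm = 0), "monomorphic")
  expect_true(is.nan(fstValue(res)))
})

test_that("statistics are invariant to locus order, individual order and
           allele relabeling", {
  set.seed(12)
  gg <- randomToyGenotypes(nGroups = 2, nPerGroup = 8, nLoci = 5,
                           nAlleles = 4, missingRate = 0.1)
  ref <- fstValue(amovaFst(gg, "pop", nPerm = 0))
  locPerm <- sample(nLoc(gg))
  expect_equal(fstValue(amovaFst(gg[, locPerm], "pop", nPerm = 0)), ref)
  indPerm <- sample(nInd(gg))
  expect_equal(fstValue(amovaFst(gg[indPerm, ], "pop", nPerm = 0)), ref)
  relab <- GroupedGenotypes(gg@allele1 * 7L + 1L, gg@allele2 * 7L + 1L,
                            groupData(gg))
  expect_equal(fstValue(amovaFst(relab, "pop", nPerm = 0)), ref)
  ## diversity is invariant too
  d1 <- diversitySummary(gg, "pop")$summary
  d2 <- diversitySummary(relab, "pop")$summary
  expect_equal(d1[, -1], d2[, -1])
})

test_that("permutation p-values are uniform under the null", {
  set.seed(13)
  nData <- 200L
  reject <- logical(nData)
  for (i in seq_len(nData)) {
    gg <- randomToyGenotypes(nGroups = 2, nPerGroup = 15, nLoci = 4,
                             nAlleles = 3)
    reject[i] <- pValue(amovaFst(gg, "pop", nPerm = 99)) <= 0.05
  }
  rate <- mean(reject)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nData))
})

test_that("pairwise FST is symmetric and matches the two-group AMOVA", {
  set.seed(14)
  gg <- randomToyGenotypes(nGroups = 3, nPerGroup = 6, nLoci = 4,
                           nAlleles = 3)
  ab <- pairwiseFst(gg, "pop", "g1", "g2", nPerm = 0)
  ba <- pairwiseFst(gg, "pop", "g2", "g1", nPerm = 0)
  expect_equal(fstValue(ab), fstValue(ba))
  sub <- gg[groupData(gg)$pop != "g3", ]
  expect_equal(fstValue(ab), fstValue(amovaFst(sub, "pop", nPerm = 0)))
  fixed <- fixedDifferencePair()
  expect_equal(fstValue(pairwiseFst(fixed, "pop", "a", "b", nPerm = 0)), 1)
})

test_that("the fast dosage FST equals the generic AMOVA engine", {
  sim <- runSimulation(SimulationConfig(nGenerations = 8L, n0 = 40L,
                                        nLoci = 15L, m12 = 0.2, m21 = 0.2,
                                        pEvent = 0.5, seed = 21))
  fast <- simFst(sim)$fst
  gg <- do.call(dosageToGenotypes, finalGenotypes(sim))
  expect_equal(fast, fstValue(amovaFst(gg, "deme", nPerm = 0)),
               tolerance = 1e-12)
})

test_that("hierarchical F-statistics nest consistently", {
  set.seed(15)
  gg <- randomToyGenotypes(nGroups = 2, nPerGroup = 10, nLoci = 6,
                           nAlleles = 4)
  ## single-level hierarchy reproduces the AMOVA FST
  h <- hierarchicalF(gg, "pop", nBoot = 0)
  expect_equal(h@table$F[1], fstValue(amovaFst(gg, "pop", nPerm = 0)),
               tolerance = 1e-12)
  expect_true(all(is.na(h@table$ciLow)))            # nBoot = 0: no CI
  ## a constant level contributes nothing
  gg@groups$year <- "2010"
  h2 <- hierarchicalF(gg, c("year", "pop"), nBoot = 0)
  expect_equal(h2@table$F[h2@table$level == "year/Total"], 0)
  expect_equal(h2@table$F[h2@table$level == "pop/Total"], h@table$F[1],
               tolerance = 1e-12)
})

test_that("locus bootstrap flags clearly differentiated levels", {
  gg <- fixedDifferencePair(nPerGroup = 8, nLoci = 6)
  set.seed(16)
  h <- hierarchicalF(gg, "pop", nBoot = 200)
  row <- h@table[h@table$level == "pop/Total", ]
  expect_true(row$significant)
  expect_gt(row$ciLow, 0)
  ## single locus: CI unavailable with a warning
  expect_warning(h1 <- hierarchicalF(gg[, 1], "pop", nBoot = 50),
                 "single locus")
  expect_true(all(is.na(h1@table$ciLow)))
})

test_that("diversity summary reproduces hand-computed values", {
  ## one locus, genotypes {AA, Aa, aa, Aa}
  a1 <- matrix(c(1L, 1L, 2L, 1L)); a2 <- matrix(c(1L, 2L, 2L, 2L))
  gg <- GroupedGenotypes(a1, a2, data.frame(pop = "p"))
  d <- diversitySummary(gg, "pop")
  expect_equal(d$summary$ho, 0.5)
  expect_equal(d$summary$hs, (8 / 7) * 0.5, tolerance = 1e-12)
  expect_equal(d$summary$na, 2)
  ## monomorphic locus
  mono <- GroupedGenotypes(matrix(3L, 4), matrix(3L, 4),
                           data.frame(pop = "p"))
  dm <- diversitySummary(mono, "pop")
  expect_equal(c(dm$summary$na, dm$summary$ho, dm$summary$hs), c(1, 0, 0))
  ## a locus with no scored calls in a group is excluded with a warning
  a1 <- cbind(c(1L, 1L, NA, NA), c(1L, 2L, 1L, 2L))
  a2 <- cbind(c(2L, 1L, NA, NA), c(1L, 2L, 2L, 2L))
  gg2 <- GroupedGenotypes(a1, a2, data.frame(pop = rep(c("x", "y"), each = 2)))
  expect_warning(d2 <- diversitySummary(gg2, "pop"), "no scored individuals")
  expect_equal(sum(d2$perLocus$group == "y"), 1L)
})

test_that("the FST estimator recovers the Balding-Nichols theta", {
  set.seed(17)
  nRep <- 15L
  est <- numeric(nRep)
  for (i in seq_len(nRep)) {
    gg <- generateSyntheticMicrosat(
      SyntheticSpec(nGroups = 2L, nPerGroup = 50L, nLoci = 20L,
                    theta = 0.2, missingRate = 0, supernumeraryRate = 0,
                    seed = 300L + i))
    est[i] <- fstValue(amovaFst(gg, "group", nPerm = 0))
  }
  expect_lt(abs(mean(est) - 0.2), 3 * sd(est) / sqrt(nRep))
})
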