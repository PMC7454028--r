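test_that("reproductive years alternate between the demes", {
  expect_equal(reproductiveYear(1, "d1"), 1L)
  expect_equal(reproductiveYear(1, "d2"), 2L)
  expect_equal(reproductiveYear(50, "d2"), 100L)
  expect_equal(reproductiveYear(7, "d1"), 13L)
  expect_error(reproductiveYear(0, "d1"), "positive integer")
})

test_that("recruit and emigrant counts follow the rounding contract", {
  expect_equal(recruitCount(1000, 1.0), 1000L)
  expect_equal(recruitCount(0, 1.3), 0L)
  expect_equal(recruitCount(1000, 1.013), 1013L)
  expect_equal(recruitCount(3, 0.5), 2L)            # 1.5 rounds away from 0
  expect_error(recruitCount(-1, 1), "non-negative")
  expect_error(recruitCount(10, -0.1), "non-negative")
  expect_equal(emigrantCount(1000, 0.5, TRUE), 500L)
  expect_equal(emigrantCount(1000, 0.5, FALSE), 0L)
  expect_equal(emigrantCount(1000, 0, TRUE), 0L)
  expect_error(emigrantCount(10, 1.2, TRUE), "\\[0, 1\\]")
})

test_that("deme initialisation draws HWE genotypes at the configured p0", {
  set.seed(1)
  fixed <- initDeme(SimulationConfig(n0 = 10L, nLoci = 5L, p0 = 1.0), "d1")
  expect_true(all(fixed$genotypes == 2L))
  empty <- initDeme(SimulationConfig(n0 = 0L, nLoci = 5L), "d2")
  expect_equal(nrow(empty$genotypes), 0L)
  expect_true(empty$extinct)
  ## binomial sampling: per-locus frequency within 3 SE of p0
  big <- initDeme(SimulationConfig(n0 = 1000L, nLoci = 100L, p0 = 0.5), "d1")
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(big$freqs) - 0.5), 3 * se / sqrt(100) * 10)  # loose
  expect_true(all(abs(big$freqs - 0.5) < 5 * se))
})

test_that("offspring sampling is binomial at the parental frequencies", {
  expect_true(all(sampleOffspringGenotypes(rep(1, 4), 20) == 2L))
  expect_true(all(sampleOffspringGenotypes(rep(0, 4), 20) == 0L))
  set.seed(2)
  g <- sampleOffspringGenotypes(rep(0.5, 20), 10000)
  obs <- colSums(g) / 20000
  expect_true(all(abs(obs - 0.5) < 0.015))           # 3 * sqrt(0.25/20000)
  expect_error(sampleOffspringGenotypes(c(0.5, 1.2), 5), "\\[0, 1\\]")
  expect_equal(dim(sampleOffspringGenotypes(c(0.5, 0.5), 0)), c(0L, 2L))
})

test_that("emigrant draws conserve individuals and clip with a warning", {
  set.seed(3)
  cohort <- matrix(sample(0:2, 30, replace = TRUE), 10, 3)
  s0 <- drawEmigrants(cohort, 0)
  expect_equal(nrow(s0$emigrants), 0L)
  expect_identical(s0$residents, cohort)
  sAll <- drawEmigrants(cohort, 10)
  expect_equal(nrow(sAll$residents), 0L)
  s4 <- drawEmigrants(cohort, 4)
  recombined <- rbind(s4$emigrants, s4$residents)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(recombined), key(cohort))         # multiset conservation
  expect_warning(sClip <- drawEmigrants(cohort, 12), "clipped")
  expect_equal(nrow(sClip$emigrants), 10L)
})

test_that("a hand-worked first generation matches the accounting equations", {
  ## m = 0.5 both ways, events always fire, deterministic growth:
  ## d1 year 1: N_R = 1000, N_E = 500, no pre-start immigrants -> N_T = 500;
  ## d2 year 2: N_R = 1000, receives d1's 500, sends 500 -> N_T = 1000.
  cfg <- SimulationConfig(nGenerations = 2L, n0 = 1000L, nLoci = 4L,
                          lambdaSd = 0, m12 = 0.5, m21 = 0.5, pEvent = 1,
                          seed = 7)
  rec <- trajectory(runSimulation(cfg))
  g1d1 <- rec[rec$deme == "d1" & rec$generation == 1, ]
  expect_equal(c(g1d1$N_R, g1d1$N_M, g1d1$N_E, g1d1$N_T),
               c(1000L, 0L, 500L, 500L))
  g1d2 <- rec[rec$deme == "d2" & rec$generation == 1, ]
  expect_equal(c(g1d2$N_R, g1d2$N_M, g1d2$N_E, g1d2$N_T),
               c(1000L, 500L, 500L, 1000L))
})

test_that("identity dynamics hold without migration or growth noise", {
  cfg <- SimulationConfig(nGenerations = 12L, n0 = 77L, nLoci = 5L,
                          lambdaSd = 0, seed = 11)
  rec <- trajectory(runSimulation(cfg))
  expect_true(all(rec$N_T == 77L))
  expect_true(all(rec$N_E == 0L & rec$N_M == 0L))
  expect_false(any(rec$extinct))
})

test_that("runs are reproducible from the seed and keep the books balanced", {
  cfg <- SimulationConfig(nGenerations = 15L, n0 = 60L, nLoci = 20L,
                          m12 = 0.3, m21 = 0.3, pEvent = 0.5, seed = 99)
  s1 <- runSimulation(cfg)
  s2 <- runSimulation(cfg)
  expect_identical(trajectory(s1), trajectory(s2))
  expect_identical(finalGenotypes(s1), finalGenotypes(s2))
  rec <- trajectory(s1)
  expect_true(all(rec$N_T == rec$N_R + rec$N_M - rec$N_E))
  expect_true(all(rec$N_T >= 0))
  ## genotype row counts equal the recorded final sizes
  fin <- rec[rec$generation == 15, ]
  expect_equal(nrow(finalGenotypes(s1)$d1), fin$N_T[fin$deme == "d1"])
  expect_equal(nrow(finalGenotypes(s1)$d2), fin$N_T[fin$deme == "d2"])
})

test_that("an extinct deme without immigration stays extinct", {
  cfg <- SimulationConfig(nGenerations = 6L, n0 = 0L, nLoci = 3L, seed = 5)
  rec <- trajectory(runSimulation(cfg))
  expect_true(all(rec$extinct))
  expect_true(all(rec$N_T == 0L))
  expect_false(any(rec$recolonized))
})

test_that("drift matches neutral theory at reduced scale", {
  ## Closed demes of size 50: after t generations the per-locus allele
  ## frequency variance is p0(1-p0)(1 - (1 - 1/(2 n0))^t) and the expected
  ## between-deme FST is 1 - (1 - 1/(2 n0))^t.
  n0 <- 50L; tGen <- 25L; nRep <- 30L
  freqs <- c(); fsts <- c()
  for (i in seq_len(nRep)) {
    sim <- runSimulation(SimulationConfig(nGenerations = tGen, n0 = n0,
                                          nLoci = 30L, lambdaSd = 0,
                                          seed = 1000L + i))
    g <- finalGenotypes(sim)
    freqs <- c(freqs, colSums(g$d1) / (2 * n0))
    fsts <- c(fsts, suppressWarnings(simFst(sim)$fst))
  }
  expVar <- 0.25 * (1 - (1 - 1 / (2 * n0))^tGen)
  obsVar <- mean((freqs - 0.5)^2)
  expect_lt(abs(obsVar - expVar),
            3 * sd((freqs - 0.5)^2) / sqrt(length(freqs)))
  expFst <- 1 - (1 - 1 / (2 * n0))^tGen
  expect_lt(abs(mean(fsts) - expFst), 3 * sd(fsts) / sqrt(nRep))
})

test_that("migration homogenizes demes (paired-seed comparison)", {
  nRep <- 50L
  fst0 <- fstM <- numeric(nRep)
  for (i in seq_len(nRep)) {
    base <- list(nGenerations = 30L, n0 = 200L, nLoci = 50L,
                 seed = 2000L + i)
    s0 <- runSimulation(do.call(SimulationConfig, base))
    sM <- runSimulation(do.call(SimulationConfig,
                                c(base, m12 = 0.4, m21 = 0.4, pEvent = 1)))
    fst0[i] <- suppressWarnings(simFst(s0)$fst)
    fstM[i] <- suppressWarnings(simFst(sM)$fst)
  }
  expect_lt(mean(fstM), mean(fst0))
})
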