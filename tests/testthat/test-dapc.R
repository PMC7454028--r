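test_that("genotype encoding expands to per-allele copy counts", {
  a1 <- matrix(c(1L, 1L, 2L), 3, 1); a2 <- matrix(c(1L, 2L, 2L), 3, 1)
  gg <- GroupedGenotypes(a1, a2, data.frame(pop = c("x", "x", "y")))
  enc <- encodeGenotypes(gg)
  raw <- sweep(enc, 2, attr(enc, "scaled:center"), "+")   # un-centre
  expect_equal(unname(raw[, 1]), c(2, 1, 0))              # allele 1 counts
  expect_equal(unname(raw[, 2]), c(0, 1, 2))              # allele 2 counts
  expect_true(all(rowSums(raw) == 2))                     # diploid rows
  ## missing calls are mean-imputed, columns stay centred
  a1[2, 1] <- NA; a2[2, 1] <- NA
  ggm <- GroupedGenotypes(a1, a2, data.frame(pop = c("x", "x", "y")))
  encm <- encodeGenotypes(ggm)
  expect_equal(unname(colMeans(encm)), c(0, 0))
  ## an all-missing locus is dropped with a warning
  a1 <- cbind(a1, NA); a2 <- cbind(a2, NA)
  gg2 <- GroupedGenotypes(a1, a2, data.frame(pop = c("x", "x", "y")))
  expect_warning(enc2 <- encodeGenotypes(gg2), "no scored calls")
})

test_that("DAPC separates fixed-difference groups perfectly", {
  gg <- fixedDifferencePair(nPerGroup = 6, nLoci = 5)
  model <- suppressMessages(fitDapc(gg, "pop", nPca = 10, nDa = 2))
  expect_equal(model@nDaRetained, 1L)        # 2 groups -> 1 axis
  s <- model@scores[, 1]
  g <- model@groups
  ## within-group variance negligible relative to the separation
  gap <- abs(mean(s[g == "a"]) - mean(s[g == "b"]))
  expect_lt(max(tapply(s, g, sd)) / gap, 1e-6)
  expect_true(max(s[g == "a"]) < min(s[g == "b"]) ||
                min(s[g == "a"]) > max(s[g == "b"]))
})

test_that("requesting more PCs than the rank silently truncates", {
  set.seed(20)
  gg <- randomToyGenotypes(nGroups = 2, nPerGroup = 5, nLoci = 3,
                           nAlleles = 2)
  model <- suppressMessages(fitDapc(gg, "pop", nPca = 500, nDa = 2))
  expect_lte(model@nPcaRetained, 10L)        # far below 500
})

test_that("centroid distances equal the mean-and-norm oracle", {
  set.seed(21)
  gg <- generateSyntheticMicrosat(SyntheticSpec(theta = 0.1, nPerGroup = 25L,
                                                seed = 33))
  model <- fitDapc(gg, "group", nPca = 20)
  d <- centroidDistance(model, "g1", "g2")
  s <- model@scores; g <- model@groups
  oracle <- sqrt(sum((colMeans(s[g == "g1", , drop = FALSE]) -
                        colMeans(s[g == "g2", , drop = FALSE]))^2))
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_equal(d, centroidDistance(model, "g2", "g1"))   # symmetry
  expect_gte(d, 0)
  expect_error(centroidDistance(model, "g1", "nope"), "unknown group")
})

test_that("identical duplicated groups sit at (near) zero distance", {
  set.seed(22)
  one <- randomToyGenotypes(nGroups = 1, nPerGroup = 12, nLoci = 8,
                            nAlleles = 4)
  dup <- GroupedGenotypes(rbind(one@allele1, one@allele1),
                          rbind(one@allele2, one@allele2),
                          data.frame(pop = rep(c("a", "b"), each = 12)))
  model <- suppressMessages(fitDapc(dup, "pop", nPca = 10))
  expect_lt(centroidDistance(model, "a", "b"), 1e-6)
})

test_that("same-distribution groups score within the permutation null", {
  set.seed(23)
  gg <- randomToyGenotypes(nGroups = 2, nPerGroup = 30, nLoci = 10,
                           nAlleles = 4)
  obs <- suppressMessages(fitDapc(gg, "pop", nPca = 15))@discrimEigenvalues[1]
  labels <- groupData(gg)$pop
  null <- replicate(49, {
    suppressMessages(
      fitDapc(encodeGenotypes(gg), sample(labels),
              nPca = 15))@discrimEigenvalues[1]
  })
  ## observed eigenvalue is not an outlier of the permutation null
  expect_gt((1 + sum(null >= obs)) / 50, 0.05)
})

test_that("centroid distance grows with the generating differentiation", {
  set.seed(24)
  thetas <- c(0.02, 0.05, 0.1, 0.2, 0.3)
  nRep <- 20L
  meanDist <- vapply(seq_along(thetas), function(k) {
    d <- vapply(seq_len(nRep), function(i) {
      gg <- generateSyntheticMicrosat(
        SyntheticSpec(nPerGroup = 40L, nLoci = 15L, theta = thetas[k],
                      missingRate = 0, supernumeraryRate = 0,
                      seed = 5000L + 100L * k + i))
      model <- suppressMessages(fitDapc(gg, "group", nPca = 25))
      centroidDistance(model, "g1", "g2")
    }, numeric(1L))
    mean(d)
  }, numeric(1L))
  expect_gt(cor(thetas, meanDist, method = "spearman"), 0.9)
})

test_that("discriminant scores agree with a reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(26)
  gg <- generateSyntheticMicrosat(
    SyntheticSpec(theta = 0.3, nPerGroup = 30L, nLoci = 12L,
                  missingRate = 0, supernumeraryRate = 0, seed = 55))
  enc <- encodeGenotypes(gg)
  g <- factor(groupData(gg)$group)
  ours <- suppressMessages(fitDapc(enc, g, nPca = 10, nDa = 1))@scores[, 1]
  pcs <- prcomp(enc)$x[, 1:10]
  ref <- predict(MASS::lda(pcs, grouping = g))$x[, 1]
  ## one discriminant axis for two groups: unique up to sign and scale
  expect_gt(abs(cor(ours, ref)), 0.999)
})
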