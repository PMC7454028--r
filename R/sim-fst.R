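## Vectorised between-deme FST for the simulator's diallelic dosage matrices.
## Same variance-component estimator as amovaFst() (two groups, individuals,
## copies within individuals), specialised to complete diallelic data so that
## the 1000-permutation significance test over thousands of individuals stays
## a single matrix product. A unit test pins this fast path to the generic
## AMOVA engine on converted data.

## per-locus variance components given group-1 reference-allele copy counts
## (cA1 may be an L x P matrix of permuted counts), fixed totals and sizes.
.dosageComponents <- function(cA1, cA, nHet, n1, n2, nIndTotal) {
  n <- n1 + n2
  cA2 <- cA - cA1
  T1 <- (cA1^2 + (n1 - cA1)^2) / n1 + (cA2^2 + (n2 - cA2)^2) / n2
  T0 <- (cA^2 + (n - cA)^2) / n
  Tind <- 2 * nIndTotal - nHet
  SS1 <- T1 - T0
  SS2 <- Tind - T1
  SSe <- n - Tind
  sigmaE <- SSe / nIndTotal
  sigma2 <- (SS2 - (nIndTotal - 2) * sigmaE) / (n - 4)
  nc <- n - (n1^2 + n2^2) / n
  sigma1 <- (SS1 - sigmaE - 2 * sigma2) / nc
  list(sigma1 = sigma1, sigma2 = sigma2, sigmaE = sigmaE)
}

#' Fast between-deme FST for simulated diallelic genotypes
#'
#' Multi-locus Weir-Cockerham/AMOVA FST between the two demes' final genotype
#' matrices, with an optional permutation test (individuals reassigned between
#' demes, deme sizes preserved). Identical estimator to [amovaFst()],
#' specialised to complete diallelic dosage data for speed.
#'
#' @param x a [PopulationTrajectory-class], or a list of two dosage matrices.
#' @param nPerm number of permutations (0 skips the test).
#' @return list with `fst` (NaN if every locus is monomorphic, NA if either
#'   deme is empty), `p` (permutation p-value or NA) and `nLociPolymorphic`.
#' @examples
#' sim <- runSimulation(SimulationConfig(nGenerations = 20L, n0 = 100L,
#'                                       nLoci = 50L, seed = 3))
#' simFst(sim, nPerm = 99)
#' @export
simFst <- function(x, nPerm = 0L) {
  if (is(x, "PopulationTrajectory")) x <- finalGenotypes(x)
  stopifnot(is.list(x), length(x) == 2L)
  X1 <- x[[1L]]; X2 <- x[[2L]]
  nPerm <- .asCount(nPerm, "nPerm")
  n1i <- nrow(X1); n2i <- nrow(X2)
  if (n1i < 2L || n2i < 2L)
    return(list(fst = NA_real_, p = NA_real_, nLociPolymorphic = 0L))
  nInd <- n1i + n2i
  n1 <- 2 * n1i; n2 <- 2 * n2i
  cA1 <- colSums(X1)
  cA <- cA1 + colSums(X2)
  poly <- cA > 0 & cA < (n1 + n2)
  if (!any(poly)) {
    .warnf("all loci monomorphic: FST undefined (NaN)")
    return(list(fst = NaN, p = NA_real_, nLociPolymorphic = 0L))
  }
  nHet <- colSums(X1 == 1L) + colSums(X2 == 1L)
  comp <- .dosageComponents(cA1, cA, nHet, n1, n2, nInd)
  fst <- sum(comp$sigma1) /
    sum(comp$sigma1 + comp$sigma2 + comp$sigmaE)
  p <- NA_real_
  if (nPerm > 0L && is.finite(fst)) {
    X <- rbind(X1, X2)
    P <- matrix(0, nInd, nPerm)
    for (j in seq_len(nPerm)) P[sample.int(nInd, n1i), j] <- 1
    CA1 <- crossprod(X, P)                       # L x nPerm group-1 counts
    compP <- .dosageComponents(CA1, cA, nHet, n1, n2, nInd)
    fstP <- colSums(compP$sigma1) /
      colSums(compP$sigma1 + compP$sigma2 + compP$sigmaE)
    p <- (1 + sum(fstP >= fst - 1e-12, na.rm = TRUE)) / (nPerm + 1)
  }
  list(fst = fst, p = p, nLociPolymorphic = as.integer(sum(poly)))
}
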