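## Independent oracles and small data builders shared across the suite.

## Brute-force two-level AMOVA (groups / individuals / copies) computed the
## textbook way: allele copies as indicator vectors over allele types, sums of
## squared deviations accumulated by explicit loops, variance components from
## the published closed-form mean-square expectations for unequal group sizes
## (n_c coefficient). Written independently of the package's Henderson-sum
## engine; multi-locus F-statistics are ratios of summed components.
bruteAmovaFst <- function(a1, a2, g) {
  g <- factor(g)
  L <- ncol(a1)
  sig <- matrix(0, L, 3)
  for (l in seq_len(L)) {
    ok <- which(!is.na(a1[, l]))
    if (!length(ok)) next
    alleles <- sort(unique(c(a1[ok, l], a2[ok, l])))
    if (length(alleles) < 2L) next
    ind <- function(v) as.numeric(alleles == v)  # indicator vector
    ys <- list()   # one entry per allele copy
    copyInd <- integer(0)  # individual of each copy
    for (i in ok) {
      ys[[length(ys) + 1L]] <- ind(a1[i, l]); copyInd <- c(copyInd, i)
      ys[[length(ys) + 1L]] <- ind(a2[i, l]); copyInd <- c(copyInd, i)
    }
    copyGrp <- g[copyInd]
    Y <- do.call(rbind, ys)
    ssd <- function(rows) {
      if (length(rows) < 2L) return(0)
      m <- colMeans(Y[rows, , drop = FALSE])
      sum(t(t(Y[rows, , drop = FALSE]) - m)^2)
    }
    ssdTotal <- ssd(seq_len(nrow(Y)))
    ssdWithinGroups <- 0
    for (gr in levels(copyGrp))
      ssdWithinGroups <- ssdWithinGroups + ssd(which(copyGrp == gr))
    ssdWithinInd <- 0
    for (i in unique(copyInd))
      ssdWithinInd <- ssdWithinInd + ssd(which(copyInd == i))
    nIndScored <- length(ok)
    nG <- table(g[ok])
    nG <- nG[nG > 0]
    r <- length(nG)
    if (r < 2L) next
    ssA <- ssdTotal - ssdWithinGroups
    ssB <- ssdWithinGroups - ssdWithinInd
    ssW <- ssdWithinInd
    msA <- ssA / (r - 1)
    msB <- ssB / (nIndScored - r)
    msW <- ssW / nIndScored
    nc <- (nIndScored - sum(nG^2) / nIndScored) / (r - 1)
    sigW <- msW
    sigB <- (msB - sigW) / 2
    sigA <- (msA - sigW - 2 * sigB) / (2 * nc)
    sig[l, ] <- c(sigA, sigB, sigW)
  }
  tot <- colSums(sig)
  list(fst = tot[1] / sum(tot), components = tot, perLocus = sig)
}

## random small multiallelic dataset with optional missing calls
randomToyGenotypes <- function(nGroups = 2, nPerGroup = 4, nLoci = 1,
                               nAlleles = 3, missingRate = 0) {
  n <- nGroups * nPerGroup
  a1 <- matrix(sample(seq_len(nAlleles) * 10L, n * nLoci, replace = TRUE),
               n, nLoci)
  a2 <- matrix(sample(seq_len(nAlleles) * 10L, n * nLoci, replace = TRUE),
               n, nLoci)
  if (missingRate > 0) {
    miss <- matrix(runif(n * nLoci) < missingRate, n, nLoci)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  GroupedGenotypes(a1, a2,
                   data.frame(pop = rep(paste0("g", seq_len(nGroups)),
                                        each = nPerGroup)))
}

## two demes fixed for alternative alleles at every locus
fixedDifferencePair <- function(nPerGroup = 5, nLoci = 4) {
  a <- matrix(1L, nPerGroup, nLoci)
  b <- matrix(2L, nPerGroup, nLoci)
  GroupedGenotypes(rbind(a, b), rbind(a, b),
                   data.frame(pop = rep(c("a", "b"), each = nPerGroup)))
}

## hand-built trajectory records for the summary-statistic operations
makeRecords <- function(sizes, deme = "d1") {
  t <- seq_along(sizes)
  extinct <- sizes == 0
  recol <- c(FALSE, extinct[-length(extinct)] & !extinct[-1])
  data.frame(deme = deme, generation = t, year = 2 * t - 1,
             N_T = sizes, N_R = sizes, N_M = 0L, N_E = 0L,
             extinct = extinct, recolonized = recol, H_S = NA_real_)
}
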