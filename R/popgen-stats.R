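## Variance-component F-statistics for co-dominant genotype data.
##
## The engine treats each allele copy as an observation in a fully nested
## random-effects design (groups / ... / individuals / copies within
## individuals) and estimates variance components by the classical ANOVA
## method for unbalanced nested classifications: sums of squares at each level
## come from squared allele-indicator deviations, and the expected-mean-square
## coefficients are the Henderson sums S_ab = sum over level-a groups of
## (sum of squared level-b subgroup sizes) / group size. For the two-level
## case (groups, individuals) this reduces exactly to the Weir-Cockerham /
## Excoffier AMOVA estimator of FST. Missing calls are excluded per locus
## (pairwise-available); multi-locus F-statistics are ratios of summed
## components, never means of per-locus ratios; negative components are
## reported raw.

## ---- core per-locus engine ------------------------------------------------

## Henderson coefficient S_{a,b}: fa coarser grouping (NULL = grand total),
## fb finer grouping, both factors over scored individuals. Sizes counted in
## allele copies (2 per individual).
.hendersonS <- function(fa, fb) {
  nb <- 2 * table(fb)
  if (is.null(fa)) return(sum(as.numeric(nb)^2) / sum(nb))
  first <- match(names(nb), as.character(fb))
  pa <- as.character(fa)[first]
  na <- 2 * table(fa)
  agg <- tapply(as.numeric(nb)^2, pa, sum)
  sum(agg / as.numeric(na[names(agg)]))
}

## T-term sum_{groups g} sum_{alleles k} c_{gk}^2 / n_g for grouping f over
## scored individuals; `alleleFac` is the factor of all 2n allele copies
## (copy order: all first copies, then all second copies).
.tTerm <- function(f, alleleFac) {
  cnt <- table(rep(f, 2L), alleleFac)
  ng <- rowSums(cnt)
  sum(rowSums(cnt^2) / ng)
}

## Variance components for ONE locus under a fully nested design.
## a1, a2: allele codes with NA = missing; levels: list of factors over ALL
## individuals, coarse -> fine (nesting enforced by the caller via
## interaction()). Returns components sigma^2 for each level, then the
## among-individuals component, then the residual (within individuals);
## zero vector for monomorphic or all-missing loci (polymorphic = FALSE).
.locusComponents <- function(a1, a2, levels) {
  M <- length(levels) + 1L                 # label levels + individual level
  out <- list(sigma2 = numeric(M + 1L), polymorphic = FALSE)
  ok <- which(!is.na(a1))
  nind <- length(ok)
  if (nind == 0L) return(out)
  alleles <- factor(c(a1[ok], a2[ok]))
  if (nlevels(alleles) < 2L) return(out)   # monomorphic: all SS are zero
  facs <- c(lapply(levels, function(f) droplevels(factor(f)[ok])),
            list(factor(seq_len(nind))))   # individual level
  n <- 2L * nind
  Tlev <- vapply(facs, .tTerm, numeric(1L), alleleFac = alleles)
  T0 <- sum(as.numeric(table(alleles))^2) / n
  r <- vapply(facs, nlevels, integer(1L))
  SS <- c(Tlev[1L] - T0, diff(Tlev))       # among each level within parent
  SSe <- n - Tlev[M]
  df <- c(r[1L] - 1L, diff(r))
  dfe <- nind
  sigmaE <- SSe / dfe
  ## coefficient matrix C[a, b] = S(F_a, F_b) - S(F_{a-1}, F_b), b >= a
  C <- matrix(0, M, M)
  for (a in seq_len(M)) {
    fa <- facs[[a]]
    faPrev <- if (a == 1L) NULL else facs[[a - 1L]]
    for (b in a:M) {
      C[a, b] <- .hendersonS(fa, facs[[b]]) - .hendersonS(faPrev, facs[[b]])
    }
  }
  sigma <- numeric(M)
  for (a in rev(seq_len(M))) {
    if (abs(C[a, a]) < 1e-12) { sigma[a] <- 0; next }
    rest <- if (a < M) sum(C[a, (a + 1L):M] * sigma[(a + 1L):M]) else 0
    sigma[a] <- (SS[a] - df[a] * sigmaE - rest) / C[a, a]
  }
  out$sigma2 <- c(sigma, sigmaE)
  out$polymorphic <- TRUE
  out
}

## Per-locus component matrix for a whole dataset: rows = loci, columns =
## hierarchy levels + individual + residual.
.componentsByLocus <- function(x, levels, levelNames) {
  a1 <- x@allele1; a2 <- x@allele2
  L <- ncol(a1)
  M <- length(levels) + 1L
  comp <- matrix(0, L, M + 1L,
                 dimnames = list(colnames(a1), c(levelNames, "Individual",
                                                 "Within")))
  poly <- logical(L)
  for (l in seq_len(L)) {
    cl <- .locusComponents(a1[, l], a2[, l], levels)
    comp[l, ] <- cl$sigma2
    poly[l] <- cl$polymorphic
  }
  list(comp = comp, polymorphic = poly)
}

.resolveGrouping <- function(x, groupBy) {
  if (is.factor(groupBy) || (is.atomic(groupBy) && length(groupBy) == nInd(x)))
    return(factor(groupBy))
  bad <- setdiff(groupBy, names(x@groups))
  if (length(bad))
    .stopf("grouping label(s) not found: %s", paste(bad, collapse = ", "))
  interaction(x@groups[groupBy], drop = TRUE, sep = ":", lex.order = TRUE)
}

## ---- AMOVA FST ------------------------------------------------------------

#' Two-level AMOVA and the multi-locus FST estimator
#'
#' Partitions total allelic variance into among-groups, among-individuals
#' within groups and within-individuals components (Weir-Cockerham /
#' Excoffier variance components) and returns the multi-locus fixation
#' indices. Significance of FST is assessed by permuting whole individuals
#' among groups (group sizes preserved), counting the observed statistic once:
#' p = (1 + #\{FST* >= FST\}) / (nPerm + 1).
#'
#' @param x a [GroupedGenotypes-class].
#' @param groupBy character vector of label columns in `groupData(x)` (joined
#'   by interaction), or a factor over individuals.
#' @param nPerm number of permutations (0 skips the test).
#' @return an [AmovaResult-class]. A completely monomorphic dataset yields
#'   `NaN` F-statistics with a warning.
#' @examples
#' gg <- generateSyntheticMicrosat(SyntheticSpec(theta = 0.2, seed = 1))
#' amovaFst(gg, "group", nPerm = 99)
#' @export
amovaFst <- function(x, groupBy, nPerm = 1000L) {
  stopifnot(is(x, "GroupedGenotypes"))
  g <- .resolveGrouping(x, groupBy)
  if (nlevels(g) < 2L) .stopf("need at least 2 groups")
  if (any(table(g) < 2L)) .stopf("each group needs at least 2 individuals")
  nPerm <- .asCount(nPerm, "nPerm")
  byLoc <- .componentsByLocus(x, list(g), "Among groups")
  res <- .amovaFromComponents(byLoc, g, nInd(x))
  obs <- res@fStatistics["FST"]
  p <- NA_real_
  if (nPerm > 0L && is.finite(obs)) {
    exceed <- 0L
    for (i in seq_len(nPerm)) {
      gp <- g[sample.int(length(g))]
      bl <- .componentsByLocus(x, list(gp), "Among groups")
      tot <- colSums(bl$comp)
      fstP <- tot[1L] / sum(tot)
      if (is.finite(fstP) && fstP >= obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (nPerm + 1)
  }
  initialize(res, pValue = p, nPerm = as.integer(nPerm))
}

## assemble an AmovaResult from per-locus components
.amovaFromComponents <- function(byLoc, g, nIndTotal) {
  comp <- byLoc$comp
  tot <- colSums(comp)
  denom <- sum(tot)
  if (!any(byLoc$polymorphic) || denom == 0) {
    .warnf("monomorphic dataset: F-statistics undefined (NaN)")
    f <- c(FST = NaN, FIS = NaN, FIT = NaN)
    denom <- NA_real_
  } else {
    f <- c(FST = tot[[1L]] / denom,
           FIS = tot[[2L]] / (tot[[2L]] + tot[[3L]]),
           FIT = (tot[[1L]] + tot[[2L]]) / denom)
  }
  r <- nlevels(g)
  components <- data.frame(
    level = c("Among groups", "Among individuals within groups",
              "Within individuals"),
    df = c(r - 1L, nIndTotal - r, nIndTotal),
    sigma2 = as.numeric(tot),
    percent = if (is.na(denom)) rep(NA_real_, 3L) else 100 * tot / denom)
  new("AmovaResult", components = components, fStatistics = f,
      pValue = NA_real_, nPerm = 0L,
      nLoci = as.integer(sum(byLoc$polymorphic)), perLocus = comp)
}

#' Pairwise FST between two groups
#'
#' [amovaFst()] restricted to two groups; symmetric in argument order.
#'
#' @param x a [GroupedGenotypes-class].
#' @param groupBy label column(s) or factor, as in [amovaFst()].
#' @param groupA,groupB the two group labels to compare.
#' @param nPerm permutations for the significance test.
#' @return an [AmovaResult-class] for the two-group comparison.
#' @export
pairwiseFst <- function(x, groupBy, groupA, groupB, nPerm = 1000L) {
  g <- .resolveGrouping(x, groupBy)
  keep <- g %in% c(groupA, groupB)
  if (!any(g == groupA) || !any(g == groupB))
    .stopf("both groups must be present in the data")
  sub <- x[keep, ]
  amovaFst(sub, droplevels(g[keep]), nPerm = nPerm)
}

## ---- hierarchical F-statistics --------------------------------------------

#' Hierarchical F-statistics with locus bootstrap
#'
#' Estimates variance components for an arbitrary nested hierarchy of labels
#' (coarse to fine, e.g. site, year, stage) plus the individual level, and
#' reports for each level the cumulative fixation index
#' F(level/Total) = (sum of components down to that level) / (total variance).
#' With a single-level hierarchy the top-level F equals the AMOVA FST of
#' [amovaFst()]. Confidence intervals (percentile 2.5-97.5%) come from
#' resampling loci with replacement; a level is flagged significant when its
#' CI excludes zero.
#'
#' @param x a [GroupedGenotypes-class].
#' @param hierarchy character vector of label columns, coarse to fine. Nesting
#'   is enforced by taking interactions, so reused labels (e.g. the same stage
#'   codes at every site) are handled correctly.
#' @param nBoot bootstrap resamples over loci (0 = point estimates only).
#' @return a [HierFResult-class].
#' @export
hierarchicalF <- function(x, hierarchy, nBoot = 1000L) {
  stopifnot(is(x, "GroupedGenotypes"))
  nBoot <- .asCount(nBoot, "nBoot")
  bad <- setdiff(hierarchy, names(x@groups))
  if (length(bad))
    .stopf("hierarchy label(s) not found: %s", paste(bad, collapse = ", "))
  k <- length(hierarchy)
  levs <- lapply(seq_len(k), function(j)
    interaction(x@groups[hierarchy[seq_len(j)]], drop = TRUE, sep = ":",
                lex.order = TRUE))
  byLoc <- .componentsByLocus(x, levs, hierarchy)
  comp <- byLoc$comp
  M <- k + 1L
  cumF <- function(totals) {
    denom <- sum(totals)
    vapply(seq_len(M), function(j) sum(totals[seq_len(j)]) / denom,
           numeric(1L))
  }
  fHat <- cumF(colSums(comp))
  ci <- matrix(NA_real_, M, 2L)
  L <- nrow(comp)
  if (nBoot > 0L) {
    if (L < 2L) {
      .warnf("single locus: bootstrap CI unavailable")
    } else {
      boot <- matrix(NA_real_, nBoot, M)
      for (b in seq_len(nBoot)) {
        idx <- sample.int(L, L, replace = TRUE)
        boot[b, ] <- cumF(colSums(comp[idx, , drop = FALSE]))
      }
      ci <- t(apply(boot, 2L, quantile, probs = c(0.025, 0.975),
                    na.rm = TRUE))
    }
  }
  levelNames <- c(paste0(hierarchy, "/Total"), "Individual/Total")
  tab <- data.frame(level = levelNames, F = fHat,
                    ciLow = ci[, 1L], ciHigh = ci[, 2L],
                    significant = !is.na(ci[, 1L]) &
                      (ci[, 1L] > 0 | ci[, 2L] < 0))
  components <- data.frame(level = c(hierarchy, "Individual", "Within"),
                           sigma2 = colSums(comp))
  new("HierFResult", table = tab, components = components,
      nBoot = as.integer(nBoot), perLocus = comp)
}

## ---- diversity ------------------------------------------------------------

#' Per-group diversity summary: n_a, H_O and Nei's unbiased H_S
#'
#' For every group: the mean number of distinct alleles per locus (n_a), the
#' mean observed heterozygosity (H_O, fraction of scored individuals that are
#' heterozygous), and the mean unbiased gene diversity
#' H_S = (2n / (2n - 1)) (1 - sum p_i^2) with n the number of scored
#' individuals, each averaged over loci with SDs across loci. Missing calls
#' are excluded locus by locus; loci with no scored individuals in a group are
#' dropped from that group's means with a warning.
#'
#' @param x a [GroupedGenotypes-class].
#' @param groupBy label column(s) or factor, as in [amovaFst()].
#' @return list with `summary` (one row per group: n, na, ho, hs and their
#'   SDs across loci), `perLocus` (long data.frame of per-group per-locus
#'   values), and `overall` (across-group means of each statistic, both
#'   unweighted and weighted by the number of scored locus-individual calls).
#' @examples
#' gg <- generateSyntheticMicrosat(SyntheticSpec(seed = 7))
#' diversitySummary(gg, "group")$summary
#' @export
diversitySummary <- function(x, groupBy) {
  stopifnot(is(x, "GroupedGenotypes"))
  g <- .resolveGrouping(x, groupBy)
  if (any(table(g) == 0L)) .stopf("empty group")
  a1 <- x@allele1; a2 <- x@allele2
  perLocus <- list()
  for (grp in levels(g)) {
    rows <- which(g == grp)
    if (!length(rows)) .stopf("empty group '%s'", grp)
    anyScored <- FALSE
    for (l in seq_len(ncol(a1))) {
      x1 <- a1[rows, l]; x2 <- a2[rows, l]
      ok <- !is.na(x1)
      n <- sum(ok)
      if (n == 0L) {
        .warnf("group '%s', locus '%s': no scored individuals; excluded",
               grp, colnames(a1)[l])
        next
      }
      anyScored <- TRUE
      alleles <- c(x1[ok], x2[ok])
      p <- as.numeric(table(alleles)) / (2 * n)
      hs <- if (n > 1L) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
      perLocus[[length(perLocus) + 1L]] <- data.frame(
        group = grp, locus = colnames(a1)[l], n = n,
        na = length(p), ho = mean(x1[ok] != x2[ok]), hs = hs)
    }
    if (!anyScored) .stopf("group '%s' has no scored calls at any locus", grp)
  }
  perLocus <- do.call(rbind, perLocus)
  summ <- do.call(rbind, lapply(split(perLocus, perLocus$group), function(d) {
    data.frame(group = d$group[1L], n = max(d$n), nLoci = nrow(d),
               na = mean(d$na), naSd = sd(d$na),
               ho = mean(d$ho), hoSd = sd(d$ho),
               hs = mean(d$hs, na.rm = TRUE), hsSd = sd(d$hs, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  w <- tapply(perLocus$n, perLocus$group, sum)[summ$group]
  overall <- data.frame(
    statistic = c("na", "ho", "hs"),
    unweightedMean = c(mean(summ$na), mean(summ$ho), mean(summ$hs)),
    unweightedSd = c(sd(summ$na), sd(summ$ho), sd(summ$hs)),
    weightedMean = c(weighted.mean(summ$na, w), weighted.mean(summ$ho, w),
                     weighted.mean(summ$hs, w)))
  list(summary = summ, perLocus = perLocus, overall = overall)
}
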