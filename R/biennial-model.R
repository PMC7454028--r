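## Forward-time demographic-genetic model of two temporally offset demes of a
## biennial, semelparous plant. Deme d1 reproduces in odd years (y = 2t - 1),
## deme d2 in even years (z = 2t). Each reproductive year a deme recruits
## N_R = lambda * N_T(year - 2) offspring by panmictic binomial sampling from
## the parental allele frequencies, loses N_E = m * N_R recruits as temporal
## migrants when a migration event fires, and gains the other deme's emigrant
## cohort of the previous year (those individuals reproduce at age 3 instead
## of 2). Bookkeeping: N_T = N_R + N_M - N_E at every generation.

#' Calendar year of a deme's t-th reproductive generation
#'
#' Deme d1 reproduces in odd years, deme d2 in even years: generation t falls
#' in year 2t - 1 for d1 and 2t for d2.
#'
#' @param t generation index (>= 1), vectorised.
#' @param deme `"d1"` or `"d2"`.
#' @return integer year(s).
#' @examples
#' reproductiveYear(1, "d1")  # 1
#' reproductiveYear(1, "d2")  # 2
#' @export
reproductiveYear <- function(t, deme = c("d1", "d2")) {
  deme <- match.arg(deme)
  if (any(t < 1) || any(t != as.integer(t)))
    .stopf("generation index t must be a positive integer")
  as.integer(if (deme == "d1") 2 * t - 1 else 2 * t)
}

#' Number of recruits from sexual reproduction
#'
#' N_R = lambda x N_T(two years back), rounded to the nearest integer (ties
#' away from zero) so that expected deme size is unbiased.
#'
#' @param nPrev parental deme size two years before (>= 0).
#' @param lambda deme growth rate (>= 0).
#' @return integer recruit count.
#' @export
recruitCount <- function(nPrev, lambda) {
  if (any(nPrev < 0) || any(lambda < 0))
    .stopf("recruitCount needs non-negative inputs")
  as.integer(roundHalfUp(lambda * nPrev))
}

#' Number of emigrating recruits
#'
#' When a migration event fires, N_E = m x N_R recruits (nearest integer)
#' leave as temporal migrants; otherwise none do. Never exceeds N_R.
#'
#' @param nR recruit count.
#' @param m temporal migration rate in \[0, 1\].
#' @param event logical; did a migration event occur this reproductive year?
#' @return integer emigrant count.
#' @export
emigrantCount <- function(nR, m, event) {
  .checkProb(m, "m")
  if (!event) return(0L)
  min(as.integer(roundHalfUp(m * nR)), as.integer(nR))
}

#' Sample offspring genotypes under panmixia
#'
#' Each offspring's copy number of the reference allele at locus l is an
#' independent Binomial(2, freqs\[l\]) draw, i.e. Hardy-Weinberg genotype
#' proportions at the parental allele frequencies.
#'
#' @param freqs per-locus allele frequencies in \[0, 1\].
#' @param n number of offspring (>= 0).
#' @return integer matrix `n x length(freqs)` with entries 0, 1, 2.
#' @export
sampleOffspringGenotypes <- function(freqs, n) {
  .checkProb(freqs, "freqs")
  n <- .asCount(n, "n")
  L <- length(freqs)
  if (n == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = L))
  matrix(rbinom(n * L, 2L, rep(freqs, each = n)), nrow = n, ncol = L)
}

#' Split a recruit cohort into emigrants and residents
#'
#' Emigrants are concrete individuals sampled uniformly without replacement
#' from the newly recruited cohort; they carry their genotypes into the other
#' deme one year later. If `nE` exceeds the cohort it is clipped with a
#' warning. No RNG is consumed when `nE` is 0.
#'
#' @param cohort integer genotype matrix (recruits x loci).
#' @param nE number of emigrants.
#' @return list with matrices `emigrants` and `residents`; row multisets union
#'   to the input cohort.
#' @export
drawEmigrants <- function(cohort, nE) {
  nE <- .asCount(nE, "nE")
  n <- nrow(cohort)
  if (nE > n) {
    .warnf("emigrant count %d exceeds cohort size %d; clipped", nE, n)
    nE <- n
  }
  if (nE == 0L)
    return(list(emigrants = cohort[integer(0), , drop = FALSE],
                residents = cohort))
  idx <- sample.int(n, nE)
  list(emigrants = cohort[idx, , drop = FALSE],
       residents = cohort[-idx, , drop = FALSE])
}

## per-locus allele frequencies of a genotype (dosage) matrix; NULL if empty
.dosageFreqs <- function(geno) {
  if (nrow(geno) == 0L) return(NULL)
  colSums(geno) / (2 * nrow(geno))
}

## Nei unbiased gene diversity averaged over diallelic loci:
## (2n / (2n - 1)) * (1 - p^2 - q^2), n individuals.
.dosageHs <- function(freqs, n) {
  if (is.null(freqs) || n == 0L) return(NA_real_)
  if (n == 1L) return(NA_real_)      # unbiased estimator undefined at n = 1
  mean((2 * n / (2 * n - 1)) * (1 - freqs^2 - (1 - freqs)^2))
}

#' Initialise a deme at Hardy-Weinberg equilibrium
#'
#' Draws `n0` individuals whose genotypes at each locus are Binomial(2, p0)
#' (HWE at the configured initial frequencies). `p0 = NA` draws one
#' uniform(0, 1) frequency per locus first.
#'
#' @param config a [SimulationConfig-class].
#' @param deme `"d1"` or `"d2"` (recorded only).
#' @return list describing the deme state: `deme`, `N_T`, genotype matrix
#'   `genotypes`, per-locus `freqs`, and `extinct` flag.
#' @export
initDeme <- function(config, deme = c("d1", "d2")) {
  deme <- match.arg(deme)
  p0 <- config@p0
  if (all(is.na(p0))) p0 <- runif(config@nLoci)
  if (length(p0) == 1L) p0 <- rep(p0, config@nLoci)
  geno <- sampleOffspringGenotypes(p0, config@n0)
  list(deme = deme, N_T = config@n0, genotypes = geno,
       freqs = .dosageFreqs(geno), extinct = config@n0 == 0L)
}

## One reproductive year of one deme.
## state:   the deme's previous reproductive state (year - 2)
## incoming: genotype matrix of the other deme's emigrants from last year
## RNG draw order is fixed: lambda, offspring, event, emigrant sampling.
.advanceDeme <- function(state, incoming, m, pEvent, config) {
  lambda <- max(0, rnorm(1L, config@lambdaMean, config@lambdaSd))
  nR <- if (state$N_T > 0L) recruitCount(state$N_T, lambda) else 0L
  offspring <- if (nR > 0L)
    sampleOffspringGenotypes(state$freqs, nR)
  else
    matrix(integer(0), 0L, config@nLoci)
  event <- runif(1L) < pEvent
  nE <- emigrantCount(nR, m, event)
  split <- drawEmigrants(offspring, nE)
  nM <- nrow(incoming)
  geno <- rbind(split$residents, incoming)
  nT <- nR + nM - nE
  stopifnot(nT == nrow(geno))
  freqs <- .dosageFreqs(geno)
  list(state = list(deme = state$deme, N_T = nT, genotypes = geno,
                    freqs = freqs, extinct = nT == 0L),
       emigrants = split$emigrants,
       counts = c(N_T = nT, N_R = nR, N_M = nM, N_E = nE),
       recolonized = state$extinct && nT > 0L,
       H_S = .dosageHs(freqs, nT))
}

#' Run the two-deme biennial simulation
#'
#' Alternates reproductive years between the demes for
#' `config@nGenerations` generations: within generation t, deme d1 reproduces
#' in year 2t - 1 and deme d2 in year 2t. Emigrants recruited by one deme in a
#' given year are held for one year and join the other deme at its next
#' reproductive year; no emigrant cohorts exist before year 1, so each deme's
#' first generation has N_M = 0. Migration events are independent
#' Bernoulli(pEvent) draws per deme-reproductive-year. Fully reproducible from
#' `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return a [PopulationTrajectory-class].
#' @examples
#' cfg <- SimulationConfig(nGenerations = 10L, n0 = 50L, nLoci = 10L, seed = 1)
#' sim <- runSimulation(cfg)
#' head(trajectory(sim))
#' @export
runSimulation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  nGen <- config@nGenerations
  d1 <- initDeme(config, "d1")
  d2 <- initDeme(config, "d2")
  emptyCohort <- matrix(integer(0), 0L, config@nLoci)
  fromD2 <- emptyCohort          # emigrants of d2 awaiting entry into d1
  rec <- vector("list", 2L * nGen)
  for (t in seq_len(nGen)) {
    up1 <- .advanceDeme(d1, fromD2, config@m12, config@pEvent, config)
    d1 <- up1$state
    fromD1 <- up1$emigrants
    up2 <- .advanceDeme(d2, fromD1, config@m21, config@pEvent, config)
    d2 <- up2$state
    fromD2 <- up2$emigrants
    rec[[2L * t - 1L]] <- data.frame(
      deme = "d1", generation = t, year = reproductiveYear(t, "d1"),
      t(up1$counts), extinct = up1$state$extinct,
      recolonized = up1$recolonized, H_S = up1$H_S)
    rec[[2L * t]] <- data.frame(
      deme = "d2", generation = t, year = reproductiveYear(t, "d2"),
      t(up2$counts), extinct = up2$state$extinct,
      recolonized = up2$recolonized, H_S = up2$H_S)
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  new("PopulationTrajectory", records = records,
      finalGenotypes = list(d1 = d1$genotypes, d2 = d2$genotypes),
      config = config)
}
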