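## Central S4 containers. All classes are lightweight wrappers around plain
## integer matrices and data.frames; accessors rather than slot access are the
## supported interface.

#' SimulationConfig: parameters of the two-deme biennial simulator
#'
#' Holds every parameter of the forward-time model: two demes of a biennial,
#' semelparous plant reproduce in alternating years (deme d1 in odd years
#' y = 2t - 1, deme d2 in even years z = 2t) and exchange temporal migrants,
#' i.e. recruits that delay reproduction by one year and therefore join the
#' other deme's mating pool.
#'
#' @slot nGenerations number of reproductive generations per deme.
#' @slot n0 initial individuals per deme.
#' @slot nLoci number of unlinked diallelic loci.
#' @slot p0 initial allele frequency per locus; either a single value recycled
#'   to all loci, a vector of length `nLoci`, or `NA_real_` meaning one
#'   uniform(0, 1) draw per locus at initialisation.
#' @slot lambdaMean,lambdaSd mean and SD of the per-year deme growth rate
#'   lambda, drawn from a normal distribution truncated at 0.
#' @slot m12,m21 temporal migration rates d1 -> d2 and d2 -> d1: the proportion
#'   of a deme's recruits that emigrate when a migration event occurs.
#' @slot pEvent probability that a migration event occurs at a given
#'   reproductive year (one independent Bernoulli draw per deme-year).
#' @slot seed RNG seed (`NA` = do not touch the RNG state).
#' @seealso [runSimulation()]
#' @export
setClass("SimulationConfig",
  representation(
    nGenerations = "integer",
    n0           = "integer",
    nLoci        = "integer",
    p0           = "numeric",
    lambdaMean   = "numeric",
    lambdaSd     = "numeric",
    m12          = "numeric",
    m21          = "numeric",
    pEvent       = "numeric",
    seed         = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenerations < 1L) msg <- c(msg, "nGenerations must be >= 1")
  if (object@n0 < 0L) msg <- c(msg, "n0 must be >= 0")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  p0 <- object@p0
  if (!(length(p0) == 1L || length(p0) == object@nLoci))
    msg <- c(msg, "p0 must have length 1 or nLoci")
  if (!all(is.na(p0)) && (any(p0 < 0, na.rm = TRUE) || any(p0 > 1, na.rm = TRUE)))
    msg <- c(msg, "p0 must lie in [0, 1] (or be NA for uniform draws)")
  for (nm in c("m12", "m21", "pEvent")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single value in [0, 1]", nm))
  }
  if (object@lambdaSd < 0) msg <- c(msg, "lambdaSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults reproduce the study conditions of the model: 100 generations per
#' deme, 1000 initial individuals per deme, 100 unlinked diallelic loci at
#' Hardy-Weinberg equilibrium with initial allele frequency 0.5, and growth
#' rates lambda ~ Normal(1, 0.01) truncated at zero.
#'
#' @param nGenerations,n0,nLoci,p0,lambdaMean,lambdaSd,m12,m21,pEvent,seed see
#'   the slots of [SimulationConfig-class]. `p0 = NA` draws one uniform(0, 1)
#'   initial frequency per locus.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(m12 = 0.4, m21 = 0.4, pEvent = 1, seed = 1)
#' cfg
#' @export
SimulationConfig <- function(nGenerations = 100L, n0 = 1000L, nLoci = 100L,
                             p0 = 0.5, lambdaMean = 1.0, lambdaSd = 0.01,
                             m12 = 0.0, m21 = 0.0, pEvent = 0.0,
                             seed = NA_integer_) {
  new("SimulationConfig",
      nGenerations = .asCount(nGenerations, "nGenerations", 1L),
      n0 = .asCount(n0, "n0", 0L),
      nLoci = .asCount(nLoci, "nLoci", 1L),
      p0 = as.numeric(p0),
      lambdaMean = as.numeric(lambdaMean),
      lambdaSd = as.numeric(lambdaSd),
      m12 = as.numeric(m12), m21 = as.numeric(m21),
      pEvent = as.numeric(pEvent),
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}

#' PopulationTrajectory: the full record of one simulation run
#'
#' @slot records data.frame with one row per deme and generation: `deme`,
#'   `generation`, `year`, `N_T`, `N_R`, `N_M`, `N_E`, `extinct`,
#'   `recolonized`, `H_S` (Nei unbiased gene diversity averaged over loci).
#' @slot finalGenotypes named list (`d1`, `d2`) of integer matrices, one row
#'   per surviving individual, one column per locus, entries counting copies
#'   of the reference allele (0, 1 or 2).
#' @slot config the [SimulationConfig-class] that produced the run.
#' @export
setClass("PopulationTrajectory",
  representation(records = "data.frame", finalGenotypes = "list",
                 config = "SimulationConfig"))

setValidity("PopulationTrajectory", function(object) {
  msg <- character()
  need <- c("deme", "generation", "year", "N_T", "N_R", "N_M", "N_E",
            "extinct", "recolonized", "H_S")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, "records must contain the standard trajectory columns")
  else {
    r <- object@records
    if (nrow(r) != 2L * object@config@nGenerations)
      msg <- c(msg, "records must have nGenerations rows per deme")
    if (any(r$N_T != r$N_R + r$N_M - r$N_E))
      msg <- c(msg, "accounting identity N_T = N_R + N_M - N_E violated")
    if (any(r$N_T < 0)) msg <- c(msg, "negative deme size")
    if (any(xor(r$extinct, r$N_T == 0L)))
      msg <- c(msg, "extinct flag must equal N_T == 0")
  }
  if (!identical(sort(names(object@finalGenotypes)), c("d1", "d2")))
    msg <- c(msg, "finalGenotypes must be a list with elements d1 and d2")
  if (length(msg)) msg else TRUE
})

#' GroupedGenotypes: grouped co-dominant multi-allelic genotypes
#'
#' The container for empirical-style genotype tables: diploid calls at
#' multi-allelic loci (microsatellites, or the simulator's diallelic loci),
#' with explicit missing data and one or more grouping labels per individual
#' (site, year, developmental stage, or deme).
#'
#' @slot allele1,allele2 integer matrices (individuals x loci); `NA` in both
#'   marks a missing call. Allele codes are arbitrary integers (e.g.
#'   microsatellite fragment sizes). The pair is unordered.
#' @slot groups data.frame of grouping labels, one row per individual.
#' @export
setClass("GroupedGenotypes",
  representation(allele1 = "matrix", allele2 = "matrix", groups = "data.frame"))

setValidity("GroupedGenotypes", function(object) {
  msg <- character()
  a1 <- object@allele1; a2 <- object@allele2
  if (!identical(dim(a1), dim(a2)))
    msg <- c(msg, "allele1 and allele2 must have identical dimensions")
  else if (any(is.na(a1) != is.na(a2)))
    msg <- c(msg, "missing calls must be missing in both allele copies")
  if (nrow(object@groups) != nrow(a1))
    msg <- c(msg, "groups must have one row per individual")
  if (is.null(colnames(a1))) msg <- c(msg, "loci must be named (colnames)")
  if (length(msg)) msg else TRUE
})

#' Construct a GroupedGenotypes object
#'
#' @param allele1,allele2 integer matrices (individuals x loci) holding the two
#'   allele copies; missing calls are `NA` in both.
#' @param groups data.frame (or named list) of grouping labels, one row per
#'   individual, e.g. `data.frame(site = ..., year = ..., stage = ...)`.
#' @param loci optional locus names (defaults to existing colnames or L1..Lk).
#' @param ids optional individual ids (defaults to rownames or I1..In).
#' @return a [GroupedGenotypes-class] object.
#' @examples
#' a1 <- matrix(c(1L, 1L, 2L, 1L), 2, 2, dimnames = list(NULL, c("A", "B")))
#' a2 <- matrix(c(1L, 2L, 2L, 2L), 2, 2, dimnames = list(NULL, c("A", "B")))
#' GroupedGenotypes(a1, a2, data.frame(pop = c("x", "y")))
#' @export
GroupedGenotypes <- function(allele1, allele2, groups, loci = NULL, ids = NULL) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  if (is.null(loci)) loci <- colnames(allele1)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(allele1)))
  if (is.null(ids)) ids <- rownames(allele1)
  if (is.null(ids)) ids <- paste0("I", seq_len(nrow(allele1)))
  ids <- make.unique(as.character(ids))
  dimnames(allele1) <- dimnames(allele2) <- list(ids, loci)
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  if (nrow(groups) == 1L && nrow(allele1) > 1L)
    groups <- groups[rep(1L, nrow(allele1)), , drop = FALSE]
  if (nrow(groups) != nrow(allele1))
    .stopf("groups must have one row per individual (got %d for %d)",
           nrow(groups), nrow(allele1))
  rownames(groups) <- ids
  new("GroupedGenotypes", allele1 = allele1, allele2 = allele2, groups = groups)
}

#' AmovaResult: variance components, F-statistics and permutation test
#'
#' @slot components data.frame with one row per level (among groups, among
#'   individuals within groups, within individuals): `df`, `sigma2` (variance
#'   component, reported raw and possibly negative), `percent` (share of the
#'   summed components, sums to 100).
#' @slot fStatistics named numeric: `FST`, `FIS`, `FIT` (multi-locus ratios of
#'   summed components).
#' @slot pValue permutation p-value for FST (NA when `nPerm = 0`).
#' @slot nPerm number of permutations of individuals among groups.
#' @slot nLoci number of polymorphic loci contributing.
#' @slot perLocus matrix of per-locus variance components (loci x 3), kept for
#'   bootstrapping and diagnostics.
#' @export
setClass("AmovaResult",
  representation(components = "data.frame", fStatistics = "numeric",
                 pValue = "numeric", nPerm = "integer", nLoci = "integer",
                 perLocus = "matrix"))

#' HierFResult: hierarchical F-statistics with locus bootstrap CIs
#'
#' @slot table data.frame with one row per hierarchy level plus the individual
#'   level: `level`, `F` (cumulative-over-total fixation index), `ciLow`,
#'   `ciHigh` (percentile 2.5-97.5% over locus bootstrap), `significant`
#'   (CI excludes zero).
#' @slot components data.frame of multi-locus variance components per level.
#' @slot nBoot number of bootstrap resamples over loci (0 = point estimates
#'   only, CI columns NA).
#' @slot perLocus array (levels+1 x loci) of per-locus variance components.
#' @export
setClass("HierFResult",
  representation(table = "data.frame", components = "data.frame",
                 nBoot = "integer", perLocus = "matrix"))

#' DapcModel: discriminant analysis of principal components
#'
#' @slot scores individual coordinates on the retained discriminant axes.
#' @slot centroids group centroids in discriminant space (groups x axes).
#' @slot groups factor of group membership.
#' @slot nPcaRetained,nDaRetained numbers of retained PCA / discriminant axes
#'   actually used (after truncation to rank and groups - 1).
#' @slot explainedVar proportion of total variance carried by each retained
#'   principal component.
#' @slot discrimEigenvalues eigenvalues of the between/within ratio on the
#'   retained axes.
#' @export
setClass("DapcModel",
  representation(scores = "matrix", centroids = "matrix", groups = "factor",
                 nPcaRetained = "integer", nDaRetained = "integer",
                 explainedVar = "numeric", discrimEigenvalues = "numeric"))

setValidity("DapcModel", function(object) {
  msg <- character()
  if (object@nDaRetained > max(1L, nlevels(object@groups) - 1L))
    msg <- c(msg, "nDaRetained must be <= number of groups - 1")
  if (nrow(object@centroids) != nlevels(object@groups))
    msg <- c(msg, "one centroid per group required")
  if (length(msg)) msg else TRUE
})

#' ScenarioSpec: the migration-rate x event-probability scenario grid
#'
#' The default grid is the full study design: migration rates 0-0.9 in steps
#' of 0.1 crossed with migration event probabilities 0-1 in steps of 0.1, 100
#' replicates each (11 000 runs). Tests and examples use reduced grids.
#'
#' @slot mGrid migration rates to explore (applied symmetrically, m12 = m21).
#' @slot pEventGrid migration event probabilities.
#' @slot nReplicates replicate simulations per cell; replicate i uses seed
#'   `baseSeed + i` in every cell, so cells are paired by seed.
#' @slot config base [SimulationConfig-class] (its m12/m21/pEvent/seed are
#'   overridden cell by cell).
#' @slot baseSeed integer base seed.
#' @slot nPerm permutations for the per-replicate FST significance test
#'   (0 skips the test).
#' @export
setClass("ScenarioSpec",
  representation(mGrid = "numeric", pEventGrid = "numeric",
                 nReplicates = "integer", config = "SimulationConfig",
                 baseSeed = "integer", nPerm = "integer"))

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (any(object@mGrid < 0 | object@mGrid > 0.9))
    msg <- c(msg, "migration rates must lie in [0, 0.9]")
  if (any(object@pEventGrid < 0 | object@pEventGrid > 1))
    msg <- c(msg, "event probabilities must lie in [0, 1]")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a scenario grid specification
#'
#' @param mGrid,pEventGrid,nReplicates,config,baseSeed,nPerm see
#'   [ScenarioSpec-class].
#' @return a validated [ScenarioSpec-class].
#' @export
ScenarioSpec <- function(mGrid = seq(0, 0.9, by = 0.1),
                         pEventGrid = seq(0, 1, by = 0.1),
                         nReplicates = 100L,
                         config = SimulationConfig(),
                         baseSeed = 1L, nPerm = 200L) {
  new("ScenarioSpec", mGrid = as.numeric(mGrid),
      pEventGrid = as.numeric(pEventGrid),
      nReplicates = .asCount(nReplicates, "nReplicates", 1L),
      config = config, baseSeed = as.integer(baseSeed),
      nPerm = .asCount(nPerm, "nPerm", 0L))
}

#' SyntheticSpec: Balding-Nichols synthetic microsatellite generator settings
#'
#' Defaults emulate the empirical data the package targets: multi-allelic
#' microsatellite loci, ~3.4% missing calls, a small fraction of
#' supernumerary (3-4 allele) calls from partial genome duplication, and weak
#' differentiation among groups.
#'
#' @slot nGroups,nPerGroup,nLoci,nAlleles data dimensions.
#' @slot theta Balding-Nichols differentiation parameter in (0, 1); group
#'   allele frequencies are Dirichlet draws around the ancestral frequencies
#'   with concentration (1 - theta) / theta.
#' @slot missingRate per-call missing probability (default 0.034).
#' @slot supernumeraryRate per-call probability of carrying one or two extra
#'   alleles (default 0.01).
#' @slot seed RNG seed.
#' @export
setClass("SyntheticSpec",
  representation(nGroups = "integer", nPerGroup = "integer", nLoci = "integer",
                 nAlleles = "integer", theta = "numeric",
                 missingRate = "numeric", supernumeraryRate = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@theta <= 0 || object@theta >= 1)
    msg <- c(msg, "theta must lie in (0, 1)")
  if (object@missingRate < 0 || object@missingRate > 1 ||
      object@supernumeraryRate < 0 || object@supernumeraryRate > 1)
    msg <- c(msg, "rates must lie in [0, 1]")
  if (object@nAlleles < 2L) msg <- c(msg, "nAlleles must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic microsatellite data specification
#'
#' @param nGroups,nPerGroup,nLoci,nAlleles,theta,missingRate,supernumeraryRate,seed
#'   see [SyntheticSpec-class].
#' @return a validated [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(nGroups = 2L, nPerGroup = 30L, nLoci = 9L,
                          nAlleles = 10L, theta = 0.05, missingRate = 0.034,
                          supernumeraryRate = 0.01, seed = NA_integer_) {
  new("SyntheticSpec",
      nGroups = .asCount(nGroups, "nGroups", 2L),
      nPerGroup = .asCount(nPerGroup, "nPerGroup", 1L),
      nLoci = .asCount(nLoci, "nLoci", 1L),
      nAlleles = .asCount(nAlleles, "nAlleles", 2L),
      theta = as.numeric(theta), missingRate = as.numeric(missingRate),
      supernumeraryRate = as.numeric(supernumeraryRate),
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}
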