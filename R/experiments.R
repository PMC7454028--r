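## Scenario-grid driver: replicate simulations over migration rates x
## migration event probabilities, per-replicate genetic summaries at the final
## generation (FST with permutation test, per-deme gene diversity, DAPC
## centroid distance), and the quadratic test for the U-shaped relationship
## between genetic distance and migration rate.

#' Stochastic growth rate of a simulated deme
#'
#' Geometric mean of the size ratios N_T(t) / N_T(t - 1) over successive
#' generations of one deme; generation pairs touching a zero size are
#' excluded (extinction is handled by the extinction rate, not the growth
#' rate).
#'
#' @param x a [PopulationTrajectory-class] or its `trajectory()` data.frame.
#' @param deme `"d1"` or `"d2"`.
#' @return the stochastic growth rate; `NA` if fewer than two positive sizes
#'   ever occur in sequence.
#' @examples
#' sim <- runSimulation(SimulationConfig(nGenerations = 10L, n0 = 100L,
#'                                       nLoci = 5L, seed = 1))
#' stochasticGrowthRate(sim, "d1")
#' @export
stochasticGrowthRate <- function(x, deme = c("d1", "d2")) {
  deme <- match.arg(deme)
  rec <- if (is(x, "PopulationTrajectory")) trajectory(x) else x
  n <- rec$N_T[rec$deme == deme][order(rec$generation[rec$deme == deme])]
  if (length(n) < 2L) .stopf("need at least 2 generations")
  ratios <- n[-1L] / n[-length(n)]
  ok <- n[-1L] > 0 & n[-length(n)] > 0
  if (!any(ok)) return(NA_real_)
  exp(mean(log(ratios[ok])))
}

#' Per-generation extinction and recolonization rates of a deme
#'
#' Extinction rate: fraction of generations whose update ends with N_T = 0.
#' Recolonization rate: fraction of generations with an extinct-to-occupied
#' transition (immigrants arriving into an empty deme).
#'
#' @inheritParams stochasticGrowthRate
#' @return named numeric `c(extinction = ..., recolonization = ...)`.
#' @export
extinctionRecolonizationRates <- function(x, deme = c("d1", "d2")) {
  deme <- match.arg(deme)
  rec <- if (is(x, "PopulationTrajectory")) trajectory(x) else x
  rows <- rec[rec$deme == deme, ]
  c(extinction = mean(rows$extinct),
    recolonization = mean(rows$recolonized))
}

## per-replicate end-of-run genetic summaries; NA where undefined
.replicateSummary <- function(sim, nPerm) {
  rec <- trajectory(sim)
  lastGen <- max(rec$generation)
  fin <- rec[rec$generation == lastGen, ]
  geno <- finalGenotypes(sim)
  alive <- vapply(geno, function(m) nrow(m) >= 2L, logical(1L))
  fst <- NA_real_; p <- NA_real_; dist <- NA_real_
  if (all(alive)) {
    f <- suppressWarnings(simFst(sim, nPerm = nPerm))
    fst <- f$fst; p <- f$p
    enc <- encodeGenotypes(rbind(geno$d1, geno$d2))
    grp <- factor(rep(c("d1", "d2"), c(nrow(geno$d1), nrow(geno$d2))))
    model <- suppressMessages(fitDapc(enc, grp, nPca = 50L, nDa = 2L))
    dist <- centroidDistance(model, "d1", "d2")
  }
  data.frame(
    growthRate = mean(c(stochasticGrowthRate(sim, "d1"),
                        stochasticGrowthRate(sim, "d2")), na.rm = TRUE),
    meanSize = mean(rec$N_T),
    extinctionRate = mean(rec$extinct),
    recolonizationRate = mean(rec$recolonized),
    hsD1 = fin$H_S[fin$deme == "d1"],
    hsD2 = fin$H_S[fin$deme == "d2"],
    bothExtinct = !any(vapply(geno, nrow, integer(1L)) > 0L),
    fst = fst, p = p, centroidDistance = dist)
}

#' Run one scenario cell: replicate simulations at fixed (m, pEvent)
#'
#' Runs `spec@nReplicates` simulations with `m12 = m21 = m` and the given
#' event probability; replicate i uses seed `baseSeed + i` (identical across
#' cells, pairing replicates between scenarios). At the final generation each
#' replicate contributes FST (with permutation p when `spec@nPerm > 0`),
#' per-deme gene diversity H_S and the DAPC centroid distance between demes.
#' Replicates with an extinct or single-individual deme are excluded from the
#' genetic summaries and counted.
#'
#' @param m temporal migration rate (applied in both directions).
#' @param pEvent migration event probability.
#' @param spec a [ScenarioSpec-class].
#' @param keepReplicates also return the per-replicate table.
#' @return one-row data.frame (the scenario summary); with
#'   `keepReplicates = TRUE`, a list with `summary` and `replicates`.
#' @export
runScenario <- function(m, pEvent, spec = ScenarioSpec(),
                        keepReplicates = FALSE) {
  stopifnot(is(spec, "ScenarioSpec"))
  validObject(spec)
  base <- spec@config
  reps <- vector("list", spec@nReplicates)
  for (i in seq_len(spec@nReplicates)) {
    cfg <- initialize(base, m12 = m, m21 = m, pEvent = pEvent,
                      seed = as.integer((spec@baseSeed + i) %%
                                          .Machine$integer.max))
    reps[[i]] <- .replicateSummary(runSimulation(cfg), spec@nPerm)
  }
  reps <- do.call(rbind, reps)
  hs <- c(reps$hsD1, reps$hsD2)
  summary <- data.frame(
    m = m, pEvent = pEvent,
    nReplicates = spec@nReplicates,
    nGenetic = sum(!is.na(reps$fst)),
    nBothExtinct = sum(reps$bothExtinct),
    meanGrowthRate = mean(reps$growthRate, na.rm = TRUE),
    meanDemeSize = mean(reps$meanSize),
    extinctionRate = mean(reps$extinctionRate),
    recolonizationRate = mean(reps$recolonizationRate),
    meanHs = mean(hs, na.rm = TRUE),
    sdHs = sd(hs, na.rm = TRUE),
    meanFst = mean(reps$fst, na.rm = TRUE),
    fracSignificant = if (spec@nPerm > 0L) mean(reps$p < 0.05, na.rm = TRUE)
                      else NA_real_,
    meanCentroidDistance = mean(reps$centroidDistance, na.rm = TRUE))
  if (keepReplicates) list(summary = summary, replicates = reps) else summary
}

#' Run the full scenario grid
#'
#' One [runScenario()] summary per (migration rate, event probability) cell.
#' Deterministic from `spec@baseSeed`; cells are independent, so the result is
#' invariant to execution order.
#'
#' @param spec a [ScenarioSpec-class].
#' @param outFile optional CSV path for the tidy summary table.
#' @param verbose log progress per cell.
#' @return data.frame with one row per grid cell.
#' @export
runGrid <- function(spec = ScenarioSpec(), outFile = NULL, verbose = FALSE) {
  stopifnot(is(spec, "ScenarioSpec"))
  cells <- expand.grid(m = spec@mGrid, pEvent = spec@pEventGrid,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (verbose)
      message(sprintf("scenario m = %.1f, pEvent = %.1f (%d/%d)",
                      cells$m[i], cells$pEvent[i], i, nrow(cells)))
    out[[i]] <- runScenario(cells$m[i], cells$pEvent[i], spec)
  }
  out <- do.call(rbind, out)
  if (!is.null(outFile)) utils::write.csv(out, outFile, row.names = FALSE)
  out
}

#' Binned distance-vs-migration curve and U-shape test
#'
#' Averages a genetic distance per migration-rate bin and tests the visual
#' U-shape claim with a quadratic fit: a U-shape is declared when the
#' quadratic coefficient is significantly positive (one-sided t test at
#' alpha) and the fitted parabola's minimum lies strictly inside the observed
#' rate range.
#'
#' @param rate numeric migration rates (one per observation, e.g. replicate).
#' @param distance matching genetic distances (e.g. DAPC centroid distances).
#' @param alpha significance level for the quadratic coefficient (0.05).
#' @return list with `curve` (mean distance per distinct rate), `fit`
#'   (quadratic coefficients), `vertex` (rate minimising the parabola),
#'   `pQuadratic` (one-sided p for a positive quadratic term) and `uShape`
#'   (logical verdict).
#' @examples
#' r <- rep(c(0, 0.25, 0.5, 0.75, 0.9), each = 10)
#' d <- (r - 0.45)^2 + rnorm(length(r), 0, 0.005)
#' migrationDistanceCurve(r, d)$uShape
#' @export
migrationDistanceCurve <- function(rate, distance, alpha = 0.05) {
  ok <- !is.na(rate) & !is.na(distance)
  rate <- rate[ok]; distance <- distance[ok]
  if (length(unique(rate)) < 3L)
    .stopf("need at least 3 distinct migration rates")
  curve <- aggregate(list(meanDistance = distance), list(rate = rate), mean)
  fit <- lm(distance ~ rate + I(rate^2))
  co <- coef(fit)
  sm <- suppressWarnings(summary(fit))$coefficients  # constant input warns
  quad <- co[["I(rate^2)"]]
  pTwo <- if ("I(rate^2)" %in% rownames(sm)) sm["I(rate^2)", 4L] else NA_real_
  pOne <- if (is.na(pTwo)) NA_real_
          else if (quad > 0) pTwo / 2 else 1 - pTwo / 2
  vertex <- if (!is.na(quad) && quad != 0) -co[["rate"]] / (2 * quad)
            else NA_real_
  uShape <- !is.na(pOne) && pOne < alpha && !is.na(vertex) &&
    vertex > min(rate) && vertex < max(rate)
  list(curve = curve, fit = co, vertex = vertex, pQuadratic = pOne,
       uShape = uShape)
}
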