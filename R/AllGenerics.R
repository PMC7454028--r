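#' @name demeflow-accessors
#' @title Accessors for demeflow S4 containers
#'
#' @description Slot access is internal; these generics are the supported
#' interface. `nInd`/`nLoc`/`locNames`/`indNames`/`groupData` query a
#' [GroupedGenotypes-class]; `trajectory`/`finalGenotypes` query a
#' [PopulationTrajectory-class]; `fstValue`/`pValue` query an
#' [AmovaResult-class].
#'
#' @param x the object.
#' @return `nInd`, `nLoc`: integer counts. `locNames`, `indNames`: character
#'   vectors. `groupData`: data.frame of labels. `trajectory`: data.frame.
#'   `finalGenotypes`: named list of genotype matrices. `fstValue`, `pValue`:
#'   single numerics.
NULL

#' @rdname demeflow-accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname demeflow-accessors
#' @export
setGeneric("nLoc", function(x) standardGeneric("nLoc"))
#' @rdname demeflow-accessors
#' @export
setGeneric("locNames", function(x) standardGeneric("locNames"))
#' @rdname demeflow-accessors
#' @export
setGeneric("indNames", function(x) standardGeneric("indNames"))
#' @rdname demeflow-accessors
#' @export
setGeneric("groupData", function(x) standardGeneric("groupData"))
#' @rdname demeflow-accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname demeflow-accessors
#' @export
setGeneric("finalGenotypes", function(x) standardGeneric("finalGenotypes"))
#' @rdname demeflow-accessors
#' @export
setGeneric("fstValue", function(x) standardGeneric("fstValue"))
#' @rdname demeflow-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname demeflow-accessors
#' @export
setMethod("nInd", "GroupedGenotypes", function(x) nrow(x@allele1))
#' @rdname demeflow-accessors
#' @export
setMethod("nLoc", "GroupedGenotypes", function(x) ncol(x@allele1))
#' @rdname demeflow-accessors
#' @export
setMethod("locNames", "GroupedGenotypes", function(x) colnames(x@allele1))
#' @rdname demeflow-accessors
#' @export
setMethod("indNames", "GroupedGenotypes", function(x) rownames(x@allele1))
#' @rdname demeflow-accessors
#' @export
setMethod("groupData", "GroupedGenotypes", function(x) x@groups)

#' @rdname demeflow-accessors
#' @export
setMethod("trajectory", "PopulationTrajectory", function(x) x@records)
#' @rdname demeflow-accessors
#' @export
setMethod("finalGenotypes", "PopulationTrajectory", function(x) x@finalGenotypes)

#' @rdname demeflow-accessors
#' @export
setMethod("fstValue", "AmovaResult", function(x) unname(x@fStatistics["FST"]))
#' @rdname demeflow-accessors
#' @export
setMethod("pValue", "AmovaResult", function(x) x@pValue)

#' Extract the two allele-copy matrices
#'
#' @param x a [GroupedGenotypes-class].
#' @return list with integer matrices `allele1` and `allele2`.
#' @export
alleleCalls <- function(x) {
  stopifnot(is(x, "GroupedGenotypes"))
  list(allele1 = x@allele1, allele2 = x@allele2)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenerations, "generations,",
      object@n0, "individuals/deme,", object@nLoci, "diallelic loci\n")
  cat(sprintf("  lambda ~ N(%g, %g) truncated at 0\n",
              object@lambdaMean, object@lambdaSd))
  cat(sprintf("  m12 = %g, m21 = %g, pEvent = %g, seed = %s\n",
              object@m12, object@m21, object@pEvent,
              ifelse(is.na(object@seed), "unset", object@seed)))
})

setMethod("show", "PopulationTrajectory", function(object) {
  r <- object@records
  cat("PopulationTrajectory:", object@config@nGenerations,
      "generations x 2 demes\n")
  fin <- r[r$generation == max(r$generation), ]
  cat(sprintf("  final sizes: d1 = %d, d2 = %d; extinctions seen: %d\n",
              fin$N_T[fin$deme == "d1"], fin$N_T[fin$deme == "d2"],
              sum(r$extinct)))
})

setMethod("show", "GroupedGenotypes", function(object) {
  miss <- mean(is.na(object@allele1))
  cat("GroupedGenotypes:", nInd(object), "individuals x", nLoc(object),
      "loci\n")
  cat(sprintf("  labels: %s; missing calls: %.1f%%\n",
              paste(names(object@groups), collapse = ", "), 100 * miss))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA over", object@nLoci, "polymorphic loci\n")
  print(cbind(object@components,
              round = round(object@components$sigma2, 5)))
  f <- object@fStatistics
  cat(sprintf("  FST = %.5f, FIS = %.5f, FIT = %.5f\n",
              f["FST"], f["FIS"], f["FIT"]))
  if (!is.na(object@pValue))
    cat(sprintf("  permutation P = %.4g (%d permutations)\n",
                object@pValue, object@nPerm))
})

setMethod("show", "HierFResult", function(object) {
  cat("Hierarchical F-statistics (", object@nBoot,
      " locus bootstraps)\n", sep = "")
  print(object@table, row.names = FALSE)
})

setMethod("show", "DapcModel", function(object) {
  cat("DAPC:", nlevels(object@groups), "groups,",
      object@nPcaRetained, "PCs retained,",
      object@nDaRetained, "discriminant axes\n")
})
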