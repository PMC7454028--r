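#' Subset a GroupedGenotypes object
#'
#' `x[i, j]` subsets individuals (`i`) and loci (`j`); group labels follow the
#' individuals.
#'
#' @param x a [GroupedGenotypes-class].
#' @param i,j individual and locus indices (logical, integer or names).
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @return a [GroupedGenotypes-class].
#' @export
setMethod("[", "GroupedGenotypes", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoc(x))
  new("GroupedGenotypes",
      allele1 = x@allele1[i, j, drop = FALSE],
      allele2 = x@allele2[i, j, drop = FALSE],
      groups = x@groups[i, , drop = FALSE])
})

#' Convert simulator dosage matrices to GroupedGenotypes
#'
#' The simulator stores diallelic genotypes as reference-allele copy counts
#' (0, 1, 2). This expands them to explicit allele pairs with codes 1
#' (reference) and 2 (alternative) so that the AMOVA, diversity and I/O
#' machinery built for empirical data applies unchanged.
#'
#' @param ... named dosage matrices, one per group (e.g. `d1 = ..., d2 = ...`),
#'   all with the same number of loci.
#' @param groupName label column name (default `"deme"`).
#' @return a [GroupedGenotypes-class] with one label column.
#' @examples
#' sim <- runSimulation(SimulationConfig(nGenerations = 5L, n0 = 20L,
#'                                       nLoci = 8L, seed = 1))
#' gg <- do.call(dosageToGenotypes, finalGenotypes(sim))
#' gg
#' @export
dosageToGenotypes <- function(..., groupName = "deme") {
  mats <- list(...)
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    .stopf("dosage matrices must be named by group")
  X <- do.call(rbind, mats)
  if (any(!X %in% 0:2)) .stopf("dosage entries must be 0, 1 or 2")
  a1 <- ifelse(X >= 1L, 1L, 2L)
  a2 <- ifelse(X == 2L, 1L, 2L)
  colnames(a1) <- colnames(a2) <-
    if (!is.null(colnames(X))) colnames(X) else paste0("L", seq_len(ncol(X)))
  groups <- data.frame(rep(names(mats), vapply(mats, nrow, integer(1L))),
                       stringsAsFactors = FALSE)
  names(groups) <- groupName
  GroupedGenotypes(a1, a2, groups)
}
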