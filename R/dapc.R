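## Discriminant Analysis of Principal Components: genotypes are encoded as
## per-allele copy counts, reduced by PCA, and linear discriminant axes are
## computed on the retained components by maximising the between-group to
## within-group variance ratio. Euclidean distances between group centroids in
## discriminant space are the working measure of genetic distance between
## demes.

#' Encode genotypes as a numeric allele-count matrix
#'
#' One column per (locus, allele) combination carrying that allele's copy
#' count (0, 1 or 2). Missing calls are imputed with the column mean and all
#' columns are centred. Columns that are missing for every individual are
#' dropped with a warning.
#'
#' @param x a [GroupedGenotypes-class], or a dosage matrix with entries
#'   0/1/2 (expanded to two columns per locus).
#' @return centred numeric matrix (individuals x allele columns) with
#'   attributes `locus` and `allele` mapping columns back to calls.
#' @export
encodeGenotypes <- function(x) {
  if (is.matrix(x)) {
    M <- cbind(x, 2 - x)
    loc <- c(colnames(x), colnames(x))
    all <- rep(c(1L, 2L), each = ncol(x))
    out <- scale(M, center = TRUE, scale = FALSE)
    attr(out, "locus") <- loc
    attr(out, "allele") <- all
    return(out)
  }
  stopifnot(is(x, "GroupedGenotypes"))
  if (nInd(x) == 0L) .stopf("empty data")
  a1 <- x@allele1; a2 <- x@allele2
  cols <- list(); locTag <- character(); allTag <- integer()
  for (l in seq_len(ncol(a1))) {
    alleles <- sort(unique(c(a1[, l], a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) {
      .warnf("locus '%s' has no scored calls; dropped", colnames(a1)[l])
      next
    }
    for (al in alleles) {
      cnt <- (a1[, l] == al) + (a2[, l] == al)
      cols[[length(cols) + 1L]] <- cnt
      locTag <- c(locTag, colnames(a1)[l])
      allTag <- c(allTag, al)
    }
  }
  M <- do.call(cbind, cols)
  colnames(M) <- paste0(locTag, ".", allTag)
  ## mean imputation of missing calls, then centring
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (any(miss)) M[miss, j] <- mean(M[!miss, j])
  }
  out <- scale(M, center = TRUE, scale = FALSE)
  attr(out, "locus") <- locTag
  attr(out, "allele") <- allTag
  out
}

#' Fit a DAPC model
#'
#' PCA (on centred, unscaled allele counts) retains `min(nPca, rank)`
#' components; linear discriminant axes on the retained components maximise
#' the between-group to within-group variance ratio, retaining
#' `min(nDa, groups - 1)` axes. A singular within-group scatter is
#' ridge-regularised with a logged epsilon, so perfectly separated groups are
#' handled.
#'
#' @param x numeric matrix from [encodeGenotypes()] (or any numeric
#'   individuals x variables matrix), or a [GroupedGenotypes-class] (encoded
#'   internally; `groups` then defaults to its label columns).
#' @param groups factor of group membership (or label column name(s) when `x`
#'   is a [GroupedGenotypes-class]).
#' @param nPca principal components to retain (silently truncated to rank).
#' @param nDa discriminant axes to retain (at most groups - 1).
#' @param scale scale columns to unit variance before PCA (default FALSE,
#'   matching common DAPC practice of centring only).
#' @return a [DapcModel-class].
#' @examples
#' gg <- generateSyntheticMicrosat(SyntheticSpec(theta = 0.2, seed = 2))
#' fitDapc(gg, "group", nPca = 20)
#' @export
fitDapc <- function(x, groups, nPca = 50L, nDa = 2L, scale = FALSE) {
  if (is(x, "GroupedGenotypes")) {
    groups <- .resolveGrouping(x, groups)
    x <- encodeGenotypes(x)
  }
  groups <- droplevels(factor(groups))
  K <- nlevels(groups)
  if (K < 2L) .stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) .stopf("each group needs >= 2 individuals")
  n <- nrow(x)
  if (length(groups) != n) .stopf("groups must match rows of x")
  xc <- scale(x, center = TRUE, scale = scale)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1L]
  rank <- sum(sv$d > tol)
  r <- min(as.integer(nPca), rank)
  scores <- sv$u[, seq_len(r), drop = FALSE] *
    rep(sv$d[seq_len(r)], each = n)
  explained <- sv$d[seq_len(r)]^2 / sum(sv$d^2)
  ## between/within scatter on retained components
  mg <- rowsum(scores, groups) / as.vector(table(groups))
  centred <- scores - mg[as.integer(groups), , drop = FALSE]
  W <- crossprod(centred) / (n - K)
  ng <- as.vector(table(groups))
  B <- crossprod(sqrt(ng) * mg) / (K - 1)
  eW <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(eW) < 1e-8 * max(abs(eW), 1)) {
    eps <- 1e-6 * mean(diag(W)) + 1e-12
    message(sprintf(
      "within-group scatter singular; ridge-regularised (epsilon = %.3g)",
      eps))
    W <- W + diag(eps, nrow(W))
  }
  ee <- eigen(solve(W, B))
  ord <- order(Re(ee$values), decreasing = TRUE)
  nAx <- min(as.integer(nDa), K - 1L)
  A <- Re(ee$vectors[, ord[seq_len(nAx)], drop = FALSE])
  ## normalise axes to unit within-group variance
  for (j in seq_len(ncol(A))) {
    s <- sqrt(drop(crossprod(A[, j], W %*% A[, j])))
    if (s > 0) A[, j] <- A[, j] / s
  }
  da <- scores %*% A
  colnames(da) <- paste0("LD", seq_len(ncol(da)))
  cent <- rowsum(da, groups) / as.vector(table(groups))
  new("DapcModel", scores = da, centroids = cent, groups = groups,
      nPcaRetained = as.integer(r), nDaRetained = as.integer(nAx),
      explainedVar = explained,
      discrimEigenvalues = Re(ee$values[ord[seq_len(nAx)]]))
}

#' Euclidean distance between two group centroids in discriminant space
#'
#' @param model a [DapcModel-class].
#' @param groupA,groupB group labels present in the model.
#' @return non-negative distance, symmetric in the arguments.
#' @export
centroidDistance <- function(model, groupA, groupB) {
  stopifnot(is(model, "DapcModel"))
  labs <- rownames(model@centroids)
  if (!(groupA %in% labs) || !(groupB %in% labs))
    .stopf("unknown group label (have: %s)", paste(labs, collapse = ", "))
  sqrt(sum((model@centroids[groupA, ] - model@centroids[groupB, ])^2))
}
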