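## Genotype file formats (GenAlEx-like CSV, STRUCTURE text, Arlequin .arp),
## the supernumerary-allele cleaning rule for partially duplicated genomes,
## and a Balding-Nichols synthetic microsatellite generator used to exercise
## the empirical pipeline with known differentiation.
##
## Dialects are fixed and parsers reject malformed input rather than guessing:
##  - GenAlEx-like CSV: line 1 = nLoci,nInd,nGroups,size1,...; line 2 = header
##    "ind,pop" + two columns per locus; 0 = missing.
##  - STRUCTURE text: line 1 = locus names (whitespace-separated); then two
##    rows per individual (one per allele copy): id, pop, alleles; -9 missing.
##  - Arlequin .arp: [Profile] + [Data]/[[Samples]] blocks, two lines per
##    individual; '?' = missing.

.groupVector <- function(x) {
  if (ncol(x@groups) == 1L) as.character(x@groups[[1L]])
  else as.character(interaction(x@groups, drop = TRUE, sep = "_",
                                lex.order = TRUE))
}

## ---- GenAlEx-like CSV -----------------------------------------------------

.writeGenalex <- function(x, path) {
  g <- .groupVector(x)
  grpLevels <- unique(g)
  sizes <- vapply(grpLevels, function(gr) sum(g == gr), integer(1L))
  loci <- locNames(x)
  header1 <- paste(c(nLoc(x), nInd(x), length(grpLevels), sizes),
                   collapse = ",")
  header2 <- paste(c("ind", "pop", rep(loci, each = 2L)), collapse = ",")
  a1 <- x@allele1; a2 <- x@allele2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  body <- vapply(seq_len(nInd(x)), function(i) {
    paste(c(indNames(x)[i], g[i], as.vector(rbind(a1[i, ], a2[i, ]))),
          collapse = ",")
  }, character(1L))
  writeLines(c(header1, header2, body), path)
  invisible(path)
}

.readGenalex <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) .stopf("%s: too short for GenAlEx dialect", path)
  h1 <- as.integer(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  if (length(h1) < 3L || any(is.na(h1)))
    .stopf("%s line 1: expected nLoci,nInd,nGroups,sizes...", path)
  nLoci <- h1[1L]; nIndD <- h1[2L]; nGrp <- h1[3L]
  if (length(h1) != 3L + nGrp)
    .stopf("%s line 1: expected %d group sizes", path, nGrp)
  h2 <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  if (length(h2) != 2L + 2L * nLoci)
    .stopf("%s line 2: expected 2 + 2 x %d columns", path, nLoci)
  loci <- h2[seq(3L, length(h2), by = 2L)]
  body <- lines[-(1:2)]
  if (length(body) != nIndD)
    .stopf("%s: declared %d individuals, found %d rows", path, nIndD,
           length(body))
  a1 <- matrix(NA_integer_, nIndD, nLoci)
  a2 <- matrix(NA_integer_, nIndD, nLoci)
  ids <- character(nIndD); pops <- character(nIndD)
  for (i in seq_len(nIndD)) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    if (length(f) != 2L + 2L * nLoci)
      .stopf("%s line %d: ragged row (%d fields, expected %d)", path, i + 2L,
             length(f), 2L + 2L * nLoci)
    ids[i] <- f[1L]; pops[i] <- f[2L]
    al <- as.integer(f[-(1:2)])
    a1[i, ] <- al[seq(1L, 2L * nLoci, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * nLoci, by = 2L)]
  }
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  GroupedGenotypes(a1, a2, data.frame(pop = pops, stringsAsFactors = FALSE),
                   loci = loci, ids = ids)
}

## ---- STRUCTURE text -------------------------------------------------------

.writeStructure <- function(x, path) {
  g <- .groupVector(x)
  popIdx <- as.integer(factor(g, levels = unique(g)))
  a1 <- x@allele1; a2 <- x@allele2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  rows <- character(2L * nInd(x))
  for (i in seq_len(nInd(x))) {
    rows[2L * i - 1L] <- paste(c(indNames(x)[i], popIdx[i], a1[i, ]),
                               collapse = " ")
    rows[2L * i] <- paste(c(indNames(x)[i], popIdx[i], a2[i, ]),
                          collapse = " ")
  }
  writeLines(c(paste(locNames(x), collapse = " "), rows), path)
  invisible(path)
}

.readStructure <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) .stopf("%s: too short for STRUCTURE dialect", path)
  loci <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  body <- lines[-1L]
  if (length(body) %% 2L != 0L)
    .stopf("%s: expected two rows per individual", path)
  nIndD <- length(body) %/% 2L
  nLoci <- length(loci)
  a1 <- matrix(NA_integer_, nIndD, nLoci)
  a2 <- matrix(NA_integer_, nIndD, nLoci)
  ids <- character(nIndD); pops <- character(nIndD)
  for (i in seq_len(nIndD)) {
    f1 <- strsplit(trimws(body[2L * i - 1L]), "[[:space:]]+")[[1L]]
    f2 <- strsplit(trimws(body[2L * i]), "[[:space:]]+")[[1L]]
    if (length(f1) != 2L + nLoci || length(f2) != 2L + nLoci)
      .stopf("%s line %d/%d: ragged row", path, 2L * i, 2L * i + 1L)
    if (f1[1L] != f2[1L])
      .stopf("%s line %d: allele-copy rows of one individual must share ids",
             path, 2L * i + 1L)
    ids[i] <- f1[1L]; pops[i] <- f1[2L]
    a1[i, ] <- as.integer(f1[-(1:2)])
    a2[i, ] <- as.integer(f2[-(1:2)])
  }
  a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  GroupedGenotypes(a1, a2, data.frame(pop = pops, stringsAsFactors = FALSE),
                   loci = loci, ids = ids)
}

## ---- Arlequin .arp --------------------------------------------------------

#' Write genotypes to an Arlequin .arp project file
#'
#' Emits a STANDARD-profile genotypic Arlequin file ([Profile] with NbSamples,
#' DataType=MICROSAT, GenotypicData=1; one [[Samples]] block per group; two
#' lines per individual; `?` = missing), the export format the simulator uses
#' for its generation-100 genotypes.
#'
#' @param x a [GroupedGenotypes-class] (use [dosageToGenotypes()] for
#'   simulated demes).
#' @param path output file.
#' @param title profile title string.
#' @return the path, invisibly.
#' @export
writeArlequin <- function(x, path, title = "demeflow export") {
  stopifnot(is(x, "GroupedGenotypes"))
  if (nInd(x) == 0L) .stopf("empty data")
  g <- .groupVector(x)
  grpLevels <- unique(g)
  out <- c("[Profile]",
           sprintf("  Title=\"%s\"", title),
           sprintf("  NbSamples=%d", length(grpLevels)),
           "  DataType=MICROSAT",
           "  GenotypicData=1",
           "  GameticPhase=0",
           "  MissingData='?'",
           "",
           "[Data]",
           "  [[Samples]]")
  a1 <- matrix(as.character(x@allele1), nInd(x))
  a2 <- matrix(as.character(x@allele2), nInd(x))
  a1[is.na(a1)] <- "?"; a2[is.na(a2)] <- "?"
  for (gr in grpLevels) {
    rows <- which(g == gr)
    out <- c(out,
             sprintf("    SampleName=\"%s\"", gr),
             sprintf("    SampleSize=%d", length(rows)),
             "    SampleData= {")
    for (i in rows) {
      out <- c(out,
               paste(c(indNames(x)[i], "1", a1[i, ]), collapse = " "),
               paste(c("", "", a2[i, ]), collapse = " "))
    }
    out <- c(out, "}")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an Arlequin .arp file written by [writeArlequin()]
#'
#' @param path .arp file.
#' @return a [GroupedGenotypes-class] with a `pop` label per sample block.
#' @export
readArlequin <- function(path) {
  lines <- readLines(path)
  getVal <- function(key) {
    ln <- grep(paste0("^\\s*", key, "="), lines, value = TRUE)
    if (!length(ln)) .stopf("%s: missing %s", path, key)
    sub(paste0("^\\s*", key, "="), "", ln)
  }
  nbSamples <- as.integer(getVal("NbSamples")[1L])
  nameLines <- grep("^\\s*SampleName=", lines)
  if (length(nameLines) != nbSamples)
    .stopf("%s: NbSamples=%d but %d SampleName entries", path, nbSamples,
           length(nameLines))
  ids <- character(); pops <- character(); rows1 <- list(); rows2 <- list()
  for (b in seq_along(nameLines)) {
    nm <- gsub("\"", "", sub("^\\s*SampleName=", "", lines[nameLines[b]]))
    sz <- as.integer(sub("^\\s*SampleSize=", "", lines[nameLines[b] + 1L]))
    dataStart <- nameLines[b] + 3L
    for (i in seq_len(sz)) {
      l1 <- strsplit(trimws(lines[dataStart + 2L * (i - 1L)]),
                     "[[:space:]]+")[[1L]]
      l2 <- strsplit(trimws(lines[dataStart + 2L * i - 1L]),
                     "[[:space:]]+")[[1L]]
      if (length(l2) != length(l1) - 2L)
        .stopf("%s: malformed genotype pair near line %d", path,
               dataStart + 2L * (i - 1L))
      ids <- c(ids, l1[1L]); pops <- c(pops, nm)
      rows1[[length(rows1) + 1L]] <- l1[-(1:2)]
      rows2[[length(rows2) + 1L]] <- l2
    }
  }
  toInt <- function(v) {
    v[v == "?"] <- NA
    as.integer(v)
  }
  a1 <- do.call(rbind, lapply(rows1, toInt))
  a2 <- do.call(rbind, lapply(rows2, toInt))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  GroupedGenotypes(a1, a2, data.frame(pop = pops, stringsAsFactors = FALSE),
                   loci = paste0("L", seq_len(ncol(a1))), ids = ids)
}

## ---- generic front ends ---------------------------------------------------

#' Read a grouped genotype table
#'
#' @param path input file.
#' @param format `"genalex-csv"`, `"structure-txt"` or `"arlequin-arp"` (see
#'   the dialect notes in the package source; parsers reject malformed input
#'   with a line number).
#' @return a [GroupedGenotypes-class].
#' @export
readGenotypeTable <- function(path,
                              format = c("genalex-csv", "structure-txt",
                                         "arlequin-arp")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  switch(format,
         "genalex-csv" = .readGenalex(path),
         "structure-txt" = .readStructure(path),
         "arlequin-arp" = readArlequin(path))
}

#' Write a grouped genotype table
#'
#' Writers and readers round-trip losslessly: write -> read -> write produces
#' a byte-identical second file.
#'
#' @param x a [GroupedGenotypes-class].
#' @param path output file.
#' @param format `"genalex-csv"`, `"structure-txt"` or `"arlequin-arp"`.
#' @return the path, invisibly.
#' @export
writeGenotypeTable <- function(x, path,
                               format = c("genalex-csv", "structure-txt",
                                          "arlequin-arp")) {
  format <- match.arg(format)
  stopifnot(is(x, "GroupedGenotypes"))
  switch(format,
         "genalex-csv" = .writeGenalex(x, path),
         "structure-txt" = .writeStructure(x, path),
         "arlequin-arp" = writeArlequin(x, path))
}

## ---- supernumerary-allele cleaning ----------------------------------------

#' Resolve supernumerary alleles to diploid calls
#'
#' Individuals with partially duplicated genomes can show 3-4 alleles at a
#' marker. The cleaning rule keeps, for each such call, the two alleles that
#' are most common within the individual's population among the alleles the
#' individual carries; single-allele calls become homozygous and two-allele
#' calls are never altered. Frequency ties break deterministically towards the
#' smaller allele code.
#'
#' @param calls long-format data.frame with columns `id`, `pop`, `locus`,
#'   `allele`: one row per observed allele per individual and locus (1-4 rows
#'   per call). Missing calls are simply absent.
#' @param includeFocal count the focal individual's own alleles in the
#'   population frequencies (default TRUE; FALSE excludes them).
#' @return a [GroupedGenotypes-class] with a `pop` label; individuals without
#'   any row at a locus carry a missing call there.
#' @examples
#' calls <- data.frame(id = c("i1", "i1", "i1", "i2", "i2"),
#'                     pop = "p1", locus = "L1",
#'                     allele = c(100L, 102L, 104L, 100L, 100L))
#' cleanSupernumeraryAlleles(calls)
#' @export
cleanSupernumeraryAlleles <- function(calls, includeFocal = TRUE) {
  need <- c("id", "pop", "locus", "allele")
  if (!all(need %in% names(calls)))
    .stopf("calls must have columns: %s", paste(need, collapse = ", "))
  ids <- unique(calls$id)
  loci <- unique(calls$locus)
  popOf <- calls$pop[match(ids, calls$id)]
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  ## population x locus allele counts over all raw rows
  for (l in loci) {
    sub <- calls[calls$locus == l, ]
    cnt <- table(sub$pop, sub$allele)
    for (i in seq_along(ids)) {
      mine <- sub$allele[sub$id == ids[i]]
      if (!length(mine)) next
      distinct <- sort(unique(mine))
      if (length(distinct) == 1L) {
        a1[i, l] <- distinct; a2[i, l] <- distinct
      } else if (length(distinct) == 2L) {
        a1[i, l] <- distinct[1L]; a2[i, l] <- distinct[2L]
      } else {
        freq <- as.numeric(cnt[popOf[i], as.character(distinct)])
        if (!includeFocal)
          freq <- freq - as.numeric(table(mine)[as.character(distinct)])
        ord <- order(-freq, distinct)           # ties -> smaller allele code
        keep <- sort(distinct[ord[1:2]])
        a1[i, l] <- keep[1L]; a2[i, l] <- keep[2L]
      }
    }
  }
  GroupedGenotypes(a1, a2, data.frame(pop = popOf, stringsAsFactors = FALSE),
                   loci = loci, ids = ids)
}

## ---- Balding-Nichols synthetic generator ----------------------------------

## Dirichlet draw via gamma variates
.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

#' Generate synthetic grouped microsatellite genotypes
#'
#' Balding-Nichols model: each locus gets ancestral allele frequencies from a
#' flat Dirichlet; each group's frequencies are a Dirichlet draw with
#' concentration `ancestral * (1 - theta) / theta`, so `theta` is the expected
#' differentiation (FST) among groups. Genotypes are Hardy-Weinberg draws from
#' the group frequencies. Missing calls are injected at `missingRate`;
#' supernumerary (3-4 allele) calls are injected at `supernumeraryRate` and
#' resolved with [cleanSupernumeraryAlleles()], mirroring the empirical
#' pipeline. Allele codes are microsatellite-like fragment sizes (150 + 2k).
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [GroupedGenotypes-class] with a `group` label column; attribute
#'   `nSupernumerary` records how many calls were injected with extra alleles.
#' @examples
#' gg <- generateSyntheticMicrosat(SyntheticSpec(theta = 0.2, seed = 11))
#' gg
#' @export
generateSyntheticMicrosat <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (!is.na(spec@seed)) set.seed(spec@seed)
  K <- spec@nGroups; nI <- spec@nPerGroup; L <- spec@nLoci; A <- spec@nAlleles
  n <- K * nI
  codes <- 150L + 2L * seq_len(A)
  conc <- (1 - spec@theta) / spec@theta
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  groupFreqs <- vector("list", L)
  for (l in seq_len(L)) {
    anc <- .rdirichlet(rep(1, A))
    pf <- vapply(seq_len(K), function(k) .rdirichlet(anc * conc), numeric(A))
    groupFreqs[[l]] <- pf                    # A x K
    for (k in seq_len(K)) {
      rows <- (k - 1L) * nI + seq_len(nI)
      a1[rows, l] <- codes[sample.int(A, nI, replace = TRUE, prob = pf[, k])]
      a2[rows, l] <- codes[sample.int(A, nI, replace = TRUE, prob = pf[, k])]
    }
  }
  group <- rep(paste0("g", seq_len(K)), each = nI)
  ids <- paste0(group, "_", rep(seq_len(nI), K))
  dimnames(a1) <- dimnames(a2) <- list(ids, paste0("L", seq_len(L)))
  ## supernumerary injection: extra alleles drawn from the group frequencies,
  ## then resolved by the population-frequency cleaning rule
  nSuper <- 0L
  if (spec@supernumeraryRate > 0) {
    super <- which(matrix(runif(n * L) < spec@supernumeraryRate, n, L))
    nSuper <- length(super)
    if (nSuper) {
      calls <- data.frame(
        id = rep(ids, L)[rep(seq_len(n * L), 2L)],
        pop = rep(group, L)[rep(seq_len(n * L), 2L)],
        locus = rep(paste0("L", seq_len(L)), each = n)[rep(seq_len(n * L), 2L)],
        allele = c(as.vector(a1), as.vector(a2)),
        stringsAsFactors = FALSE)
      extra <- lapply(super, function(cell) {
        i <- (cell - 1L) %% n + 1L
        l <- (cell - 1L) %/% n + 1L
        k <- (i - 1L) %/% nI + 1L
        nExtra <- sample(1:2, 1L)
        data.frame(id = ids[i], pop = group[i], locus = paste0("L", l),
                   allele = codes[sample.int(A, nExtra, replace = TRUE,
                                             prob = groupFreqs[[l]][, k])],
                   stringsAsFactors = FALSE)
      })
      calls <- rbind(calls, do.call(rbind, extra))
      cleaned <- cleanSupernumeraryAlleles(calls)
      ## restore original individual/locus order
      a1 <- cleaned@allele1[ids, paste0("L", seq_len(L)), drop = FALSE]
      a2 <- cleaned@allele2[ids, paste0("L", seq_len(L)), drop = FALSE]
    }
  }
  if (spec@missingRate > 0) {
    miss <- matrix(runif(n * L) < spec@missingRate, n, L)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  out <- GroupedGenotypes(a1, a2,
                          data.frame(group = group, stringsAsFactors = FALSE),
                          loci = paste0("L", seq_len(L)), ids = ids)
  attr(out, "nSupernumerary") <- nSuper
  out
}
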