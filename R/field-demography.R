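## Estimators of temporal migration and mortality from tagged-rosette fates.
## A cohort of 1-year-old vegetative rosettes is tagged and resampled one year
## later; each survivor either flowered (completed the biennial cycle) or
## stayed vegetative for a third year, i.e. became a temporal migrant into the
## other deme. The package ships the study's transition count table as a
## plain-CSV fixture (inst/extdata/tagged_rosette_transitions.csv).

#' Temporal migration rate from tagged-rosette fates
#'
#' The percentage of surviving rosettes that remained vegetative one year
#' after tagging, i.e. delayed reproduction and migrated into the other deme:
#' `100 * vegetative / (vegetative + reproductive)`. Rounded half-up to
#' `digits` decimals (2, matching field-table display); `digits = NULL`
#' returns the raw value.
#'
#' @param vegetative,reproductive counts of resampled survivors that stayed
#'   vegetative / became reproductive (vectorised).
#' @param digits display rounding (default 2; `NULL` = no rounding).
#' @return percentage(s) in \[0, 100\]; `NA` where there were no survivors.
#' @examples
#' temporalMigrationRate(33, 28)  # 54.10
#' temporalMigrationRate(12, 69)  # 14.81
#' @export
temporalMigrationRate <- function(vegetative, reproductive, digits = 2L) {
  if (any(vegetative < 0, na.rm = TRUE) || any(reproductive < 0, na.rm = TRUE))
    .stopf("counts must be non-negative")
  survivors <- vegetative + reproductive
  rate <- ifelse(!is.na(survivors) & survivors > 0,
                 100 * vegetative / survivors, NA_real_)
  if (is.null(digits)) rate else roundHalfUp(rate, digits)
}

#' Mortality rate of tagged vegetative rosettes
#'
#' `100 * dead / resampled`, the percentage of resampled tagged rosettes found
#' dead one year later.
#'
#' @param dead,resampled counts (vectorised); `resampled` must be positive for
#'   a defined rate.
#' @param digits display rounding (default 2; `NULL` = no rounding).
#' @return percentage(s); `NA` where `resampled` is 0 or counts are missing.
#' @examples
#' mortalityRate(42, 103)  # 40.78
#' @export
mortalityRate <- function(dead, resampled, digits = 2L) {
  if (any(dead < 0, na.rm = TRUE) || any(resampled < 0, na.rm = TRUE))
    .stopf("counts must be non-negative")
  rate <- ifelse(!is.na(resampled) & resampled > 0 & !is.na(dead),
                 100 * dead / resampled, NA_real_)
  if (is.null(digits)) rate else roundHalfUp(rate, digits)
}

#' Read a tagged-rosette transition count table
#'
#' CSV with columns `transition`, `site`, `resampled`, `dead`, `vegetative`,
#' `reproductive`. Every complete row must satisfy
#' `resampled = dead + vegetative + reproductive` (hard error otherwise);
#' rows with missing counts (sites where fates could not be scored) are kept
#' and excluded from rate computations downstream.
#'
#' @param path CSV file; defaults to the packaged study table.
#' @return data.frame of validated records with appended `mortality` and
#'   `migration` rate columns (unrounded percentages, `NA` where undefined).
#' @examples
#' tab <- readTransitionTable()
#' tab[tab$transition == "2010-11", ]
#' @export
readTransitionTable <- function(path = system.file(
  "extdata", "tagged_rosette_transitions.csv", package = "demeflow")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transition", "site", "resampled", "dead", "vegetative",
            "reproductive")
  if (!all(need %in% names(tab)))
    .stopf("transition table must have columns: %s",
           paste(need, collapse = ", "))
  complete <- stats::complete.cases(tab[, c("resampled", "dead", "vegetative",
                                            "reproductive")])
  bad <- complete & (tab$resampled !=
                       tab$dead + tab$vegetative + tab$reproductive)
  if (any(bad))
    .stopf("row %s: resampled != dead + vegetative + reproductive",
           paste(which(bad), collapse = ", "))
  if (any(complete & (tab$resampled < 0 | tab$dead < 0 | tab$vegetative < 0 |
                        tab$reproductive < 0)))
    .stopf("negative counts")
  tab$mortality <- mortalityRate(tab$dead, tab$resampled, digits = NULL)
  tab$migration <- temporalMigrationRate(tab$vegetative, tab$reproductive,
                                         digits = NULL)
  tab
}

#' Across-site summary of per-transition rates
#'
#' Unweighted mean and sample SD (n - 1 denominator) across sites of the
#' mortality and temporal migration rates within one transition. Sites with
#' undefined rates are excluded; fewer than 2 valid sites leaves the SD `NA`.
#'
#' @param records data.frame from [readTransitionTable()].
#' @param transition transition label, e.g. `"2011-12"`.
#' @return data.frame with one row per statistic (`mortality`, `migration`):
#'   `mean`, `sd`, `nSites` (unrounded; round for display).
#' @examples
#' transitionSummary(readTransitionTable(), "2011-12")
#' @export
transitionSummary <- function(records, transition) {
  rows <- records[records$transition == transition, ]
  if (!nrow(rows)) .stopf("unknown transition '%s'", transition)
  one <- function(v) {
    v <- v[!is.na(v)]
    data.frame(mean = mean(v), sd = if (length(v) >= 2L) sd(v) else NA_real_,
               nSites = length(v))
  }
  out <- rbind(one(rows$mortality), one(rows$migration))
  cbind(statistic = c("mortality", "migration"), transition = transition, out)
}
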