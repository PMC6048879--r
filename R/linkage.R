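# Exposure assignment, privacy-preserving patient matching, and the
# participation/coverage accounting. Linked records deliberately carry no
# postcode and no location: the match is performed here as a pure
# postcode -> values lookup, mirroring a within-practice script that
# transmits only the patient identifier and the element values.

MATCH_CATEGORIES <- c("complete", "partial", "no_coverage",
                      "postcode_unmatched", "no_postcode",
                      "practice_not_participating")

#' Detection-limit based element exclusion
#'
#' An element is retained only if the fraction of survey samples flagged
#' below the detection limit is strictly less than `threshold`. With the
#' default threshold of 0.75 an element censored in three quarters of the
#' samples (as cadmium is in the national survey) is dropped before
#' interpolation.
#'
#' @param survey a [SoilSurvey-class].
#' @param threshold exclusion threshold on the below-detection fraction
#'   (default 0.75).
#' @return list with `retained` / `excluded` element vectors and
#'   `fraction`, the named per-element below-detection fraction.
#' @export
lodExclusion <- function(survey, threshold = 0.75) {
  if (ncol(survey) == 0) stop("survey is empty", call. = FALSE)
  bd <- belowDetection(survey)
  conc <- concentrations(survey)
  absent <- rowSums(!is.na(conc) | bd) == 0
  if (any(absent))
    stop("element(s) absent from all samples: ",
         paste(rownames(bd)[absent], collapse = ", "), call. = FALSE)
  frac <- rowMeans(bd)
  keep <- frac < threshold
  list(retained = rownames(bd)[keep],
       excluded = rownames(bd)[!keep],
       fraction = frac)
}

#' Assign exposures to postcodes from element surfaces
#'
#' Looks up each postcode centroid in every element surface
#' ([valueAtCentroid()]); a centroid outside coverage yields a missing
#' value for that element. All surfaces must share origin, cell size and
#' dimensions.
#'
#' @param postcodes postcode data.frame (see [readPostcodes()]).
#' @param surfaces named list of [ConcentrationSurface-class], one per
#'   element.
#' @return an [ExposureTable-class], one row per postcode.
#' @export
assignExposures <- function(postcodes, surfaces) {
  postcodes <- validatePostcodes(postcodes)
  stopifnot(length(surfaces) > 0)
  ref <- surfaces[[1]]
  for (s in surfaces) {
    if (!isTRUE(all.equal(surfaceOrigin(s), surfaceOrigin(ref))) ||
        surfaceCellSize(s) != surfaceCellSize(ref) ||
        !identical(dim(surfaceValues(s)), dim(surfaceValues(ref))))
      stop("surfaces must share extent and cell size", call. = FALSE)
  }
  elements <- vapply(surfaces, surfaceElement, character(1))
  if (any(!nzchar(elements))) elements <- names(surfaces)
  m <- vapply(surfaces, function(s) {
    valueAtCentroid(s, postcodes$x, postcodes$y)
  }, numeric(nrow(postcodes)))
  m <- matrix(m, nrow = nrow(postcodes),
              dimnames = list(postcodes$code, elements))
  exposureTable(m)
}

#' Link patients to exposures by postcode
#'
#' Reproduces the within-practice matching: each patient at a
#' participating practice has their (current or last known) postcode
#' looked up in the exposure table; on a hit, a record with the patient
#' identifier and the element values -- and deliberately nothing else --
#' is emitted. Every patient receives exactly one match outcome:
#'
#' * `practice_not_participating` -- the practice is inactive or declined;
#'   no lookup is attempted.
#' * `no_postcode` -- blank postcode field.
#' * `postcode_unmatched` -- postcode absent from the exposure table
#'   (invalid, out-dated, or newly created).
#' * `no_coverage` -- postcode present but all element values missing.
#' * `partial` / `complete` -- record emitted with at least one / all
#'   element values present.
#'
#' @param patients patient data.frame (see [readPatients()]).
#' @param practices practice data.frame.
#' @param exposures an [ExposureTable-class].
#' @return list with `records` (data.frame: `patient_id` plus one numeric
#'   column per element; no postcode, no location) and `outcomes`
#'   (data.frame: `patient_id`, `category`).
#' @export
linkPatients <- function(patients, practices, exposures) {
  patients <- validatePatients(patients)
  practices <- validatePractices(practices)
  unknown <- !patients$practice_id %in% practices$practice_id
  if (any(unknown))
    stop("unknown practice id: ",
         patients$practice_id[which(unknown)[1L]], call. = FALSE)
  m <- exposureMatrix(exposures)
  elements <- colnames(m)

  participating <- practices$participating[
    match(patients$practice_id, practices$practice_id)]
  pc <- patients$postcode
  hasPc <- !is.na(pc) & nzchar(pc)
  row <- match(pc, rownames(m))

  nPresent <- rep(NA_integer_, nrow(patients))
  found <- hasPc & !is.na(row)
  nPresent[found] <- rowSums(!is.na(m[row[found], , drop = FALSE]))

  category <- rep(NA_character_, nrow(patients))
  category[!participating] <- "practice_not_participating"
  idx <- participating
  category[idx & !hasPc] <- "no_postcode"
  category[idx & hasPc & is.na(row)] <- "postcode_unmatched"
  category[idx & found & nPresent == 0] <- "no_coverage"
  category[idx & found & nPresent == length(elements)] <- "complete"
  category[idx & found & nPresent > 0 &
             nPresent < length(elements)] <- "partial"

  emit <- category %in% c("complete", "partial")
  records <- data.frame(patient_id = patients$patient_id[emit],
                        stringsAsFactors = FALSE)
  vals <- m[row[emit], , drop = FALSE]
  rownames(vals) <- NULL  # postcode codes must not leak via rownames
  for (el in elements) records[[el]] <- vals[, el]

  outcomes <- data.frame(patient_id = patients$patient_id,
                         category = factor(category,
                                           levels = MATCH_CATEGORIES),
                         stringsAsFactors = FALSE)
  list(records = records, outcomes = outcomes)
}

#' Practice participation report
#'
#' Per-region counts of participating and active practices with an
#' integer percentage (half-up rounding), plus a Total row computed from
#' the summed counts. Regions with no active practice are suppressed with
#' a warning.
#'
#' @param practices practice data.frame.
#' @return data.frame: `region_id`, `participating`, `active`, `pct`.
#' @examples
#' pr <- data.frame(practice_id = as.character(1:9), region_id = "R1",
#'                  active = TRUE,
#'                  participating = c(rep(TRUE, 7), FALSE, FALSE))
#' participationReport(pr)  # 7 of 9 active -> 78%
#' @export
participationReport <- function(practices) {
  practices <- validatePractices(practices)
  regions <- sort(unique(practices$region_id))
  rows <- lapply(regions, function(r) {
    p <- practices[practices$region_id == r, ]
    data.frame(region_id = r,
               participating = sum(p$participating),
               active = sum(p$active),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  empty <- df$active == 0
  if (any(empty)) {
    warning("region(s) with no active practices suppressed: ",
            paste(df$region_id[empty], collapse = ", "), call. = FALSE)
    df <- df[!empty, , drop = FALSE]
  }
  total <- data.frame(region_id = "Total",
                      participating = sum(df$participating),
                      active = sum(df$active),
                      stringsAsFactors = FALSE)
  df <- rbind(df, total)
  df$pct <- roundHalfUp(100 * df$participating / df$active)
  rownames(df) <- NULL
  df
}

#' Coverage report from match outcomes
#'
#' The Tables 2/3-style accounting: per region (taken from the patient's
#' practice) the number of patients at active practices, at linkage
#' (participating) practices, with partial (at least one element) data and
#' with complete (all elements) data. Percentages use the table's
#' denominators -- at-linkage as a share of total-at-active, partial and
#' complete as shares of at-linkage -- rounded half-up to one decimal.
#' Patients at inactive practices are excluded from all denominators.
#'
#' @param outcomes outcome data.frame from [linkPatients()].
#' @param patients patient data.frame (same order/ids as outcomes).
#' @param practices practice data.frame.
#' @param decimals decimal places for the percentages (default 1).
#' @return data.frame with one row per region plus a Total row.
#' @export
coverageReport <- function(outcomes, patients, practices, decimals = 1) {
  practices <- validatePractices(practices)
  stopifnot(identical(outcomes$patient_id, patients$patient_id))
  pidx <- match(patients$practice_id, practices$practice_id)
  region <- practices$region_id[pidx]
  active <- practices$active[pidx]
  participating <- practices$participating[pidx]
  cat <- as.character(outcomes$category)

  keep <- active
  region <- region[keep]; participating <- participating[keep]
  cat <- cat[keep]
  regions <- sort(unique(region))
  counts <- lapply(regions, function(r) {
    sel <- region == r
    data.frame(region_id = r,
               total = sum(sel),
               at_linkage = sum(sel & participating),
               partial = sum(sel & cat %in% c("partial", "complete")),
               complete = sum(sel & cat == "complete"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, counts)
  coverageReportFromCounts(df$region_id, df$total, df$at_linkage,
                           df$partial, df$complete, decimals = decimals)
}

#' Coverage report from pre-tabulated counts
#'
#' Assembles the same report as [coverageReport()] directly from regional
#' counts (e.g. counts printed in a published table), appending a Total
#' row from the column sums and computing all percentages with the
#' report's denominators and rounding rule.
#'
#' @param region region identifiers.
#' @param total patients at active practices.
#' @param atLinkage patients at participating practices.
#' @param partial patients with at least one element value.
#' @param complete patients with all element values.
#' @param decimals decimal places (default 1).
#' @param addTotal append a Total row (default TRUE).
#' @return data.frame: counts plus `at_linkage_pct`, `partial_pct`,
#'   `complete_pct`.
#' @export
coverageReportFromCounts <- function(region, total, atLinkage, partial,
                                     complete, decimals = 1,
                                     addTotal = TRUE) {
  df <- data.frame(region_id = as.character(region), total = total,
                   at_linkage = atLinkage, partial = partial,
                   complete = complete, stringsAsFactors = FALSE)
  bad <- with(df, complete > partial | partial > at_linkage |
                at_linkage > total)
  if (any(bad))
    rowStop(firstBad(bad),
            "counts must satisfy complete <= partial <= at_linkage <= total")
  if (addTotal) {
    df <- rbind(df, data.frame(region_id = "Total",
                               total = sum(df$total),
                               at_linkage = sum(df$at_linkage),
                               partial = sum(df$partial),
                               complete = sum(df$complete),
                               stringsAsFactors = FALSE))
  }
  df$at_linkage_pct <- roundHalfUp(100 * df$at_linkage / df$total, decimals)
  df$partial_pct <- roundHalfUp(100 * df$partial / df$at_linkage, decimals)
  df$complete_pct <- roundHalfUp(100 * df$complete / df$at_linkage,
                                 decimals)
  rownames(df) <- NULL
  df
}

#' Tabulate match outcomes
#'
#' @param outcomes outcome data.frame from [linkPatients()].
#' @return named integer vector over the six categories (sums to the
#'   patient count).
#' @export
outcomeCounts <- function(outcomes) {
  table(outcomes$category)
}

#' Write a report data.frame as JSON
#'
#' @param report any report data.frame.
#' @param path output path.
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
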