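# Representativeness validation: apportion census output-area populations
# equally over their postcodes (border-crossing postcodes first randomly
# assigned to a single candidate area), summarize the population-weighted
# exposure distribution expected in each region, summarize the observed
# distribution among patients alive and actively registered on the census
# date, and compare the two.

#' Apportion census populations to postcodes
#'
#' Border-crossing postcodes are first assigned to exactly one of their
#' candidate output areas, uniformly at random under `seed`; each output
#' area's population is then split equally among its assigned postcodes.
#' The split is computed as successive differences of the cumulative
#' shares, so the total population is conserved exactly in floating point,
#' for any seed.
#'
#' @param oas output-area data.frame (`oa_id`, `region_id`, `population`).
#' @param postcodes postcode data.frame; each postcode's home `oa_id` is
#'   its sole candidate unless listed in `borderCrossers`.
#' @param borderCrossers optional data.frame (`code`, `candidate_oas`
#'   semicolon-separated) as from [readBorderCrossers()].
#' @param seed RNG seed for the border-crosser assignment.
#' @return data.frame: `code`, `population`, `assigned_oa`,
#'   `assigned_region`.
#' @export
apportionPopulation <- function(oas, postcodes, borderCrossers = NULL,
                                seed = 1) {
  oas <- validateOutputAreas(oas)
  postcodes <- validatePostcodes(postcodes)
  assigned <- postcodes$oa_id
  names(assigned) <- postcodes$code
  if (!is.null(borderCrossers) && nrow(borderCrossers) > 0) {
    unknown <- !borderCrossers$code %in% postcodes$code
    if (any(unknown))
      stop("border crosser for unknown postcode '",
           borderCrossers$code[which(unknown)[1L]], "'", call. = FALSE)
    cands <- strsplit(borderCrossers$candidate_oas, ";", fixed = TRUE)
    withSeed(seed, {
      for (k in seq_along(cands)) {
        cc <- trimws(cands[[k]])
        if (any(!cc %in% oas$oa_id))
          stop("candidate area not in output-area table for postcode '",
               borderCrossers$code[k], "'", call. = FALSE)
        assigned[borderCrossers$code[k]] <-
          cc[sample.int(length(cc), 1L)]
      }
    })
  }
  if (any(!assigned %in% oas$oa_id))
    stop("postcode assigned to unknown output area '",
         assigned[!assigned %in% oas$oa_id][1L], "'", call. = FALSE)

  nByOa <- table(assigned)
  emptyOa <- oas$oa_id[oas$population > 0 &
                         !oas$oa_id %in% names(nByOa)]
  if (length(emptyOa) > 0)
    stop("output area with population but no assigned postcode: ",
         emptyOa[1L], call. = FALSE)

  out <- data.frame(code = postcodes$code,
                    population = 0,
                    assigned_oa = unname(assigned),
                    stringsAsFactors = FALSE)
  for (oa in names(nByOa)) {
    pop <- oas$population[oas$oa_id == oa]
    n <- as.integer(nByOa[[oa]])
    # telescoping split: shares sum to pop exactly
    shares <- diff(pop * (0:n) / n)
    out$population[out$assigned_oa == oa] <- shares
  }
  out$assigned_region <- oas$region_id[match(out$assigned_oa, oas$oa_id)]
  out
}

#' Is a patient alive and actively registered on a date?
#'
#' True iff `registration_start <= date`, the registration is open or ends
#' on/after `date`, and the patient is alive past `date` (a death on the
#' date itself counts as not alive). Registration starting exactly on the
#' date counts as registered.
#'
#' @param patients patient data.frame.
#' @param date a `Date` (e.g. the 2011 census date, `"2011-03-27"`).
#' @return logical vector.
#' @export
activeOn <- function(patients, date = as.Date("2011-03-27")) {
  date <- as.Date(date)
  patients$registration_start <= date &
    (is.na(patients$registration_end) |
       patients$registration_end >= date) &
    (is.na(patients$death_date) | patients$death_date > date)
}

#' Weighted quantiles (merged Hazen convention)
#'
#' Weights are aggregated over tied values, then each distinct value gets
#' the Hazen midpoint plotting position `(C_i - w_i/2) / W` on the weighted
#' empirical CDF, and quantiles are read off by linear interpolation
#' (clamped to the data range in the tails). Merging ties first makes the
#' result exactly invariant under weight rescaling and exactly equal to
#' the summary of the expanded value list when weights are integer
#' frequencies; on tie-free equally weighted data it coincides with
#' `quantile(type = 5)`.
#'
#' @param values numeric vector (finite).
#' @param weights non-negative weights, at least one positive.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles.
#' @export
weightedQuantile <- function(values, weights, probs) {
  stopifnot(length(values) == length(weights))
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  keep <- weights > 0
  if (!any(keep)) stop("all weights are zero", call. = FALSE)
  ord <- order(values[keep])
  v <- values[keep][ord]; w <- weights[keep][ord]
  grp <- cumsum(c(TRUE, diff(v) > 0))    # ties share a group
  uv <- v[!duplicated(grp)]
  uw <- as.numeric(rowsum(w, grp))       # reordered by integer group
  W <- sum(uw)
  cw <- cumsum(uw)
  pos <- (cw - uw / 2) / W
  vapply(probs, function(p) {
    if (p <= pos[1]) return(uv[1])
    if (p >= pos[length(pos)]) return(uv[length(uv)])
    stats::approx(pos, uv, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' Weighted five-number boxplot summary
#'
#' Median and quartiles by [weightedQuantile()]; whiskers are Tukey
#' adjacent values -- the most extreme observations (with positive weight)
#' inside the `fence * IQR` fences, clamped to the quartiles so the
#' five numbers are always ordered.
#'
#' @param values numeric vector.
#' @param weights non-negative weights, at least one positive.
#' @param fence whisker fence multiplier (default 1.5).
#' @return one-row data.frame: `median`, `q1`, `q3`, `lower_adjacent`,
#'   `upper_adjacent`, `effective_weight`.
#' @export
weightedSummary <- function(values, weights = rep(1, length(values)),
                            fence = 1.5) {
  q <- weightedQuantile(values, weights, c(0.25, 0.5, 0.75))
  iqr <- q[3] - q[1]
  v <- values[weights > 0]
  lo <- min(v[v >= q[1] - fence * iqr])
  hi <- max(v[v <= q[3] + fence * iqr])
  data.frame(median = q[2], q1 = q[1], q3 = q[3],
             lower_adjacent = min(lo, q[1]),
             upper_adjacent = max(hi, q[3]),
             effective_weight = sum(weights))
}

#' Expected exposure distributions by region and element
#'
#' Population-weighted summaries of the postcode exposure values: for each
#' region and element, postcodes with a non-missing value contribute their
#' apportioned population as weight (missing values are excluded
#' element-wise). Strata with no positively weighted non-missing value are
#' omitted.
#'
#' @param exposures an [ExposureTable-class].
#' @param pops apportioned populations from [apportionPopulation()].
#' @param fence whisker fence multiplier.
#' @return data.frame: `region_id`, `element`, and the five summary
#'   columns plus `effective_weight`.
#' @export
expectedDistribution <- function(exposures, pops, fence = 1.5) {
  m <- exposureMatrix(exposures)
  idx <- match(pops$code, rownames(m))
  if (anyNA(idx))
    stop("postcode '", pops$code[which(is.na(idx))[1L]],
         "' has no exposure row", call. = FALSE)
  strataSummaries(m[idx, , drop = FALSE], pops$assigned_region,
                  pops$population, fence)
}

#' Observed exposure distributions among active patients
#'
#' Unit-weight summaries of linked patient exposures, restricted to
#' patients alive and actively registered on `censusDate`; the region is
#' the patient's practice's region. Missing element values are excluded
#' element-wise.
#'
#' @param records linked records from [linkPatients()].
#' @param patients patient data.frame.
#' @param practices practice data.frame.
#' @param censusDate census reference date (default `"2011-03-27"`).
#' @param fence whisker fence multiplier.
#' @return data.frame as for [expectedDistribution()];
#'   `effective_weight` is the patient count of the stratum.
#' @export
observedDistribution <- function(records, patients, practices,
                                 censusDate = as.Date("2011-03-27"),
                                 fence = 1.5) {
  patients <- validatePatients(patients)
  practices <- validatePractices(practices)
  pidx <- match(records$patient_id, patients$patient_id)
  if (anyNA(pidx)) stop("record for unknown patient", call. = FALSE)
  act <- activeOn(patients, censusDate)[pidx]
  rec <- records[act, , drop = FALSE]
  if (nrow(rec) == 0) {
    return(data.frame(region_id = character(), element = character(),
                      median = numeric(), q1 = numeric(), q3 = numeric(),
                      lower_adjacent = numeric(),
                      upper_adjacent = numeric(),
                      effective_weight = numeric()))
  }
  region <- practices$region_id[match(
    patients$practice_id[pidx][act], practices$practice_id)]
  m <- as.matrix(rec[, setdiff(names(rec), "patient_id"), drop = FALSE])
  strataSummaries(m, region, rep(1, nrow(m)), fence)
}

# shared stratified summary kernel: matrix of values (rows = units,
# cols = elements), one region and weight per row
strataSummaries <- function(m, region, weight, fence) {
  rows <- list()
  for (r in sort(unique(region))) {
    sel <- region == r
    for (el in colnames(m)) {
      v <- m[sel, el]
      w <- weight[sel]
      ok <- !is.na(v) & w > 0
      if (!any(ok)) next
      s <- weightedSummary(v[ok], w[ok], fence)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(region_id = r, element = el,
                         stringsAsFactors = FALSE), s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare expected and observed exposure distributions
#'
#' Joins the two summary tables on region and element and reports the
#' observed/expected ratios of the medians, of the interquartile ranges
#' and of the whisker spans (upper minus lower adjacent value). The
#' restriction flag is raised when the observed whisker span is below
#' `restrictionFraction` of the expected span -- the signature of a
#' patient cohort that samples only part of a region's exposure range.
#' Strata present on only one side are marked incomparable.
#'
#' @param expected summary data.frame from [expectedDistribution()].
#' @param observed summary data.frame from [observedDistribution()].
#' @param restrictionFraction span-ratio threshold (default 0.5).
#' @return data.frame: `region_id`, `element`, `comparable`,
#'   `median_ratio`, `iqr_ratio`, `span_ratio`, `restricted`.
#' @export
compareDistributions <- function(expected, observed,
                                 restrictionFraction = 0.5) {
  keyE <- paste(expected$region_id, expected$element, sep = "\r")
  keyO <- paste(observed$region_id, observed$element, sep = "\r")
  keys <- union(keyE, keyO)
  rows <- lapply(keys, function(k) {
    e <- expected[keyE == k, , drop = FALSE]
    o <- observed[keyO == k, , drop = FALSE]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    base <- data.frame(region_id = parts[1], element = parts[2],
                       stringsAsFactors = FALSE)
    if (nrow(e) == 0 || nrow(o) == 0) {
      return(cbind(base, comparable = FALSE, median_ratio = NA_real_,
                   iqr_ratio = NA_real_, span_ratio = NA_real_,
                   restricted = NA))
    }
    spanE <- e$upper_adjacent - e$lower_adjacent
    spanO <- o$upper_adjacent - o$lower_adjacent
    ratio <- function(a, b) if (b == 0) ifelse(a == 0, 1, Inf) else a / b
    spanRatio <- ratio(spanO, spanE)
    cbind(base, comparable = TRUE,
          median_ratio = ratio(o$median, e$median),
          iqr_ratio = ratio(o$q3 - o$q1, e$q3 - e$q1),
          span_ratio = spanRatio,
          restricted = spanRatio < restrictionFraction)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region_id, out$element), ]
  rownames(out) <- NULL
  out
}
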