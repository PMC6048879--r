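# Self-contained study-level experiments: a one-call linkage study on a
# synthetic configuration, and the representativeness recovery experiment
# used to exercise the distribution comparison under a known truth.

#' Run a complete linkage study in memory
#'
#' Generates a synthetic study, applies detection-limit exclusion, builds
#' one IDW surface per retained element over the configured domain,
#' assigns postcode exposures, links patients and assembles the
#' participation and coverage reports -- without writing any files.
#'
#' @param config a [SimConfig-class].
#' @param seed master seed.
#' @param idw an [IdwConfig-class].
#' @return list: `study`, `retained`, `surfaces`, `exposures`, `linked`
#'   (records + outcomes), `participation`, `coverage`.
#' @export
linkageStudy <- function(config, seed, idw = idwConfig()) {
  study <- simulateStudy(config, seed)
  lod <- lodExclusion(study$survey)
  extent <- c(0, config@domainKm[1] * 1000, 0, config@domainKm[2] * 1000)
  surfaces <- surfacesFromSurvey(study$survey, lod$retained, extent, idw)
  exposures <- assignExposures(study$postcodes, surfaces)
  linked <- linkPatients(study$patients, study$practices, exposures)
  list(study = study, retained = lod$retained, surfaces = surfaces,
       exposures = exposures, linked = linked,
       participation = participationReport(study$practices),
       coverage = coverageReport(linked$outcomes, study$patients,
                                 study$practices))
}

#' Representativeness recovery experiment
#'
#' Builds a small synthetic population (four regions, four elements,
#' truth-field exposures at postcode centroids), apportions census
#' populations, and compares the expected population-weighted exposure
#' distributions against a simulated patient cohort:
#'
#' * with `restrict = FALSE` the cohort samples every region's postcodes
#'   in proportion to their apportioned population (a uniform sample of
#'   the population), so observed and expected distributions should agree
#'   and no restriction flag should fire beyond noise;
#' * with `restrict = TRUE` the cohort of region `"R11"` is drawn only
#'   from its lowest-exposure compact cluster (the output area with the
#'   smallest maximum first-element exposure, minimum three postcodes),
#'   emulating a region covered by very few participating practices, so
#'   the restriction flag should fire there and only there.
#'
#' @param seed replicate seed (drives fields, geography, apportionment
#'   and cohort sampling through derived seeds).
#' @param restrict restrict region `"R11"`'s cohort (default FALSE).
#' @param nPerRegion cohort size per region (default 400).
#' @return the [compareDistributions()] data.frame, with the restricted
#'   region name in attribute `"restricted_region"` when restricted.
#' @export
representativenessRun <- function(seed, restrict = FALSE,
                                  nPerRegion = 400) {
  cfg <- simConfig(domainKm = c(10, 10),
                   urbanCentres = data.frame(x = 5, y = 5, radius = 2),
                   elements = transform(defaultElementParams()[1:4, ],
                                        corrLengthKm = 3),
                   postcodeCount = 300, oaTargetSize = 6,
                   practiceCount = 4, patientCount = 10)
  fields <- generateTruthFields(cfg, seed)
  geo <- generatePostcodesAndOas(cfg, derivedSeed(seed, "postcodes"))
  pc <- geo$postcodes
  m <- vapply(names(fields), function(el) fields[[el]](pc$x, pc$y),
              numeric(nrow(pc)))
  rownames(m) <- pc$code
  exposures <- exposureTable(m)
  pops <- apportionPopulation(geo$oas, pc, geo$borderCrossers,
                              derivedSeed(seed, "apportion"))
  expected <- expectedDistribution(exposures, pops)

  regions <- sort(unique(pops$assigned_region))
  practices <- data.frame(
    practice_id = paste0("PR", seq_along(regions)),
    region_id = regions, active = TRUE, participating = TRUE,
    stringsAsFactors = FALSE)
  cohort <- withSeed(derivedSeed(seed, "cohort"), {
    rows <- lapply(seq_along(regions), function(k) {
      r <- regions[k]
      sel <- which(pops$assigned_region == r)
      if (restrict && r == "R11") {
        v <- m[match(pops$code[sel], rownames(m)), 1]
        oa <- pops$assigned_oa[sel]
        oaMax <- tapply(v, oa, max)
        oaSize <- table(oa)
        eligible <- names(oaSize)[oaSize >= 3]
        lowOa <- eligible[which.min(oaMax[eligible])]
        sel <- sel[oa == lowOa]
      }
      idx <- sel[sample.int(length(sel), nPerRegion, replace = TRUE,
                            prob = pops$population[sel])]
      data.frame(practice_id = practices$practice_id[k],
                 postcode = pops$code[idx], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(nrow(cohort))),
    practice_id = cohort$practice_id,
    postcode = cohort$postcode,
    registration_start = as.Date("2005-01-01"),
    registration_end = as.Date(NA),
    death_date = as.Date(NA),
    stringsAsFactors = FALSE)
  linked <- linkPatients(patients, practices, exposures)
  observed <- observedDistribution(linked$records, patients, practices)
  cmp <- compareDistributions(expected, observed)
  if (restrict) attr(cmp, "restricted_region") <- "R11"
  cmp
}
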