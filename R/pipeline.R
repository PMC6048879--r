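# End-to-end orchestration: simulate -> interpolate -> link -> validate,
# with every artifact written to disk, plain-text report renderings, and a
# manifest (seeds, digests, timings) written last so a completed run is
# fully described by its output directory.

#' Run the full pipeline on a synthetic study
#'
#' Executes, in order: study generation, detection-limit element
#' exclusion, IDW surface construction for every retained element,
#' nearest-site distance QC, postcode exposure assignment, patient
#' linkage, participation and coverage reports, census population
#' apportionment, expected and observed exposure distributions, and their
#' comparison. Any stage failure aborts with an error naming the stage.
#' The manifest is written last.
#'
#' @param config a [SimConfig-class].
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir output directory (created if needed).
#' @param idw an [IdwConfig-class] (default: 5 km radius, 1 km cells).
#' @return the manifest, invisibly (list: seeds, stage timings, file
#'   digests, headline figures).
#' @export
runPipeline <- function(config, seed, outDir, idw = idwConfig()) {
  validObject(config)
  if (config@practiceCount < 1)
    stop("pipeline config error: zero practices", call. = FALSE)
  if (config@patientCount < 1)
    stop("pipeline config error: zero patients", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  study <- stage("simulate", simulateStudy(config, seed, outDir))
  lod <- stage("lod_exclusion", lodExclusion(study$survey))

  W <- config@domainKm[1] * 1000; H <- config@domainKm[2] * 1000
  surfaces <- stage("interpolate", {
    s <- surfacesFromSurvey(study$survey, lod$retained,
                            extent = c(0, W, 0, H), config = idw)
    for (el in names(s))
      writeRaster(s[[el]], file.path(outDir, paste0("surface_", el,
                                                    ".asc")))
    s
  })
  qc <- stage("distance_qc", {
    sites <- siteInfo(study$survey)
    nearestSiteDistances(study$postcodes$x, study$postcodes$y,
                         sites$x, sites$y)
  })
  exposures <- stage("assign_exposures", {
    e <- assignExposures(study$postcodes, surfaces)
    writeExposures(e, file.path(outDir, "exposures.csv"))
    e
  })
  linked <- stage("link_patients",
                  linkPatients(study$patients, study$practices, exposures))
  stage("write_records", {
    utils::write.csv(linked$records,
                     file.path(outDir, "linked_records.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(linked$outcomes,
                     file.path(outDir, "match_outcomes.csv"),
                     row.names = FALSE, quote = FALSE)
  })
  participation <- stage("participation_report", {
    r <- participationReport(study$practices)
    writeReportJson(r, file.path(outDir, "participation.json"))
    writeLines(renderParticipationTable(r),
               file.path(outDir, "participation.txt"))
    r
  })
  coverage <- stage("coverage_report", {
    r <- coverageReport(linked$outcomes, study$patients, study$practices)
    writeReportJson(r, file.path(outDir, "coverage.json"))
    writeLines(renderCoverageTable(r), file.path(outDir, "coverage.txt"))
    r
  })
  pops <- stage("apportion", apportionPopulation(
    study$oas, study$postcodes, study$borderCrossers,
    seed = derivedSeed(seed, "apportion")))
  comparison <- stage("validate", {
    expd <- expectedDistribution(exposures, pops)
    obsd <- observedDistribution(linked$records, study$patients,
                                 study$practices, config@censusDate)
    cmp <- compareDistributions(expd, obsd)
    writeReportJson(expd, file.path(outDir, "expected_distributions.json"))
    writeReportJson(obsd, file.path(outDir, "observed_distributions.json"))
    writeReportJson(cmp, file.path(outDir, "distribution_comparison.json"))
    cmp
  })

  manifest <- list(
    tool = "geolink",
    version = as.character(utils::packageVersion("geolink")),
    seed = seed,
    stage_seeds = list(
      survey = derivedSeed(seed, "survey"),
      postcodes = derivedSeed(seed, "postcodes"),
      population = derivedSeed(seed, "population"),
      apportion = derivedSeed(seed, "apportion")),
    config = list(
      domain_km = config@domainKm,
      n_postcodes = nrow(study$postcodes),
      n_sites = ncol(study$survey),
      n_practices = nrow(study$practices),
      n_patients = nrow(study$patients),
      elements_retained = lod$retained,
      elements_excluded = lod$excluded,
      idw_radius_m = idw@radius, idw_power = idw@power,
      idw_cell_m = idw@cellSize),
    distance_qc_km = as.list(round(qc$quantiles / 1000, 3)),
    participation_total_pct =
      participation$pct[participation$region_id == "Total"],
    coverage_total = as.list(
      coverage[coverage$region_id == "Total",
               c("at_linkage_pct", "partial_pct", "complete_pct")]),
    restricted_strata = sum(comparison$restricted, na.rm = TRUE),
    timings_s = timings)
  files <- list.files(outDir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$digests <- as.list(tools::md5sum(files))
  names(manifest$digests) <- basename(files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a participation report as an aligned text table
#'
#' One row per region plus the Total row, counts and an integer
#' percentage.
#'
#' @param report data.frame from [participationReport()].
#' @return character vector of lines.
#' @export
renderParticipationTable <- function(report) {
  header <- c("Region", "Participating", "Active", "Rate (%)")
  body <- cbind(report$region_id,
                fmtCount(report$participating),
                fmtCount(report$active),
                formatC(report$pct, format = "d"))
  alignColumns(header, body)
}

#' Render a coverage report as an aligned text table
#'
#' One row per region plus the Total row; counts carry their percentage
#' in parentheses with one decimal, e.g. `6,243,363 (91.5%)`.
#'
#' @param report data.frame from [coverageReport()] or
#'   [coverageReportFromCounts()].
#' @return character vector of lines.
#' @export
renderCoverageTable <- function(report) {
  cp <- function(n, pct) sprintf("%s (%s%%)", fmtCount(n),
                                 formatC(pct, format = "f", digits = 1))
  header <- c("Region", "Total patients", "At linkage practices",
              "Partial data", "Complete data")
  body <- cbind(report$region_id,
                fmtCount(report$total),
                cp(report$at_linkage, report$at_linkage_pct),
                cp(report$partial, report$partial_pct),
                cp(report$complete, report$complete_pct))
  alignColumns(header, body)
}

# pad columns to equal width; first column left-aligned, rest right
alignColumns <- function(header, body) {
  m <- rbind(header, body)
  widths <- apply(nchar(m), 2, max)
  lines <- apply(m, 1, function(row) {
    cells <- vapply(seq_along(row), function(j) {
      formatC(row[j], width = widths[j],
              flag = if (j == 1) "-" else "")
    }, character(1))
    paste(cells, collapse = "  ")
  })
  unname(lines)
}
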