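# Delimited-text readers and writers for every tabular artifact shared by
# the pipeline, with row-addressed validation, plus ESRI ASCII grid I/O for
# rasters. All files are UTF-8 CSV with a header row; below-detection
# survey cells are encoded by a sentinel string (default "<LOD").

#' Read a soil survey table
#'
#' Expects columns `site_id`, `x`, `y`, `source` and one column per panel
#' element. Element cells equal to `sentinel` are carried as
#' below-detection flags, not numbers.
#'
#' @param path CSV file path.
#' @param panel an [ElementPanel-class] naming the element columns.
#' @param sentinel string marking below-detection cells (default `"<LOD"`).
#' @return a [SoilSurvey-class].
#' @export
readSurvey <- function(path, panel = defaultElementPanel(),
                       sentinel = "<LOD") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  requireColumns(df, c("site_id", "x", "y", "source", panelElements(panel)),
                 "survey")
  n <- nrow(df)
  x <- parseNumericColumn(df$x, "x", "survey")
  y <- parseNumericColumn(df$y, "y", "survey")
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) rowStop(firstBad(bad), "non-finite coordinate")
  src <- trimws(df$source)
  bad <- !src %in% c("urban", "rural", "background")
  if (any(bad)) rowStop(firstBad(bad), "unknown source '%s'",
                        src[firstBad(bad)])
  elements <- panelElements(panel)
  conc <- matrix(NA_real_, length(elements), n,
                 dimnames = list(elements, NULL))
  bd <- matrix(FALSE, length(elements), n,
               dimnames = list(elements, NULL))
  for (el in elements) {
    raw <- trimws(df[[el]])
    isBd <- !is.na(raw) & raw == sentinel
    bd[el, ] <- isBd
    raw[isBd] <- NA
    v <- parseNumericColumn(raw, el, "survey")
    neg <- !is.na(v) & v < 0
    if (any(neg)) rowStop(firstBad(neg),
                          "negative concentration %g for element %s",
                          v[firstBad(neg)], el)
    conc[el, ] <- v
  }
  sites <- data.frame(site_id = df$site_id, x = x, y = y, source = src,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sites$site_id))
    rowStop(which(duplicated(sites$site_id))[1L], "duplicate site_id '%s'",
            sites$site_id[duplicated(sites$site_id)][1L])
  SoilSurvey(sites, conc, bd, panel)
}

#' Write a soil survey table
#'
#' Inverse of [readSurvey()] up to float formatting.
#'
#' @param survey a [SoilSurvey-class].
#' @param path output CSV path.
#' @param sentinel below-detection sentinel string.
#' @export
writeSurvey <- function(survey, path, sentinel = "<LOD") {
  sites <- siteInfo(survey)
  conc <- concentrations(survey)
  bd <- belowDetection(survey)
  out <- data.frame(site_id = sites$site_id,
                    x = sites$x, y = sites$y, source = sites$source,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (el in rownames(conc)) {
    col <- formatC(conc[el, ], format = "g", digits = 12)
    col[bd[el, ]] <- sentinel
    out[[el]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the postcode table
#'
#' Columns: `code`, `x`, `y` (centroid, metres), `oa_id`, `region_id`,
#' `address_count`.
#'
#' @param path CSV path.
#' @return data.frame of postcodes.
#' @export
readPostcodes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  requireColumns(df, c("code", "x", "y", "oa_id", "region_id",
                       "address_count"), "postcode")
  df$x <- parseNumericColumn(df$x, "x", "postcode")
  df$y <- parseNumericColumn(df$y, "y", "postcode")
  df$address_count <- parseNumericColumn(df$address_count, "address_count",
                                         "postcode")
  validatePostcodes(df)
}

#' @rdname readPostcodes
#' @param postcodes postcode data.frame.
#' @export
writePostcodes <- function(postcodes, path) {
  utils::write.csv(validatePostcodes(postcodes), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a postcode table
#'
#' @param df candidate data.frame.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validatePostcodes <- function(df) {
  requireColumns(df, c("code", "x", "y", "oa_id", "region_id",
                       "address_count"), "postcode")
  bad <- is.na(df$code) | !nzchar(df$code)
  if (any(bad)) rowStop(firstBad(bad), "empty postcode code")
  if (anyDuplicated(df$code))
    rowStop(which(duplicated(df$code))[1L], "duplicate postcode '%s'",
            df$code[duplicated(df$code)][1L])
  bad <- !is.finite(df$x) | !is.finite(df$y)
  if (any(bad)) rowStop(firstBad(bad), "non-finite centroid")
  bad <- !is.finite(df$address_count) | df$address_count < 1 |
    df$address_count != floor(df$address_count)
  if (any(bad)) rowStop(firstBad(bad), "address_count must be a positive integer")
  df
}

#' Read / write the census output-area table
#'
#' Columns: `oa_id`, `region_id`, `population`.
#'
#' @param path CSV path.
#' @return data.frame of output areas.
#' @export
readOutputAreas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  requireColumns(df, c("oa_id", "region_id", "population"), "output-area")
  df$population <- parseNumericColumn(df$population, "population",
                                      "output-area")
  validateOutputAreas(df)
}

#' @rdname readOutputAreas
#' @param oas output-area data.frame.
#' @export
writeOutputAreas <- function(oas, path) {
  utils::write.csv(validateOutputAreas(oas), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate an output-area table
#' @param df candidate data.frame.
#' @return the validated data.frame.
#' @export
validateOutputAreas <- function(df) {
  requireColumns(df, c("oa_id", "region_id", "population"), "output-area")
  if (anyDuplicated(df$oa_id))
    rowStop(which(duplicated(df$oa_id))[1L], "duplicate oa_id '%s'",
            df$oa_id[duplicated(df$oa_id)][1L])
  bad <- !is.finite(df$population) | df$population < 0
  if (any(bad)) rowStop(firstBad(bad), "population must be >= 0")
  df
}

#' Read / write the practice table
#'
#' Columns: `practice_id`, `region_id`, `active`, `participating`
#' (TRUE/FALSE). A participating practice must be active.
#'
#' @param path CSV path.
#' @return data.frame of practices.
#' @export
readPractices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  requireColumns(df, c("practice_id", "region_id", "active",
                       "participating"), "practice")
  df$active <- toupper(trimws(df$active)) == "TRUE"
  df$participating <- toupper(trimws(df$participating)) == "TRUE"
  validatePractices(df)
}

#' @rdname readPractices
#' @param practices practice data.frame.
#' @export
writePractices <- function(practices, path) {
  utils::write.csv(validatePractices(practices), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a practice table
#' @param df candidate data.frame.
#' @return the validated data.frame.
#' @export
validatePractices <- function(df) {
  requireColumns(df, c("practice_id", "region_id", "active",
                       "participating"), "practice")
  if (anyDuplicated(df$practice_id))
    rowStop(which(duplicated(df$practice_id))[1L],
            "duplicate practice_id '%s'",
            df$practice_id[duplicated(df$practice_id)][1L])
  bad <- df$participating & !df$active
  if (any(bad))
    rowStop(firstBad(bad), "practice '%s' participates but is not active",
            df$practice_id[firstBad(bad)])
  df
}

#' Read / write the patient table
#'
#' Columns: `patient_id`, `practice_id`, `postcode` (may be blank),
#' `registration_start`, `registration_end` (blank = open), `death_date`
#' (blank = alive). Dates are ISO-8601.
#'
#' @param path CSV path.
#' @return data.frame of patients with `Date` columns.
#' @export
readPatients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  requireColumns(df, c("patient_id", "practice_id", "postcode",
                       "registration_start", "registration_end",
                       "death_date"), "patient")
  df$postcode <- trimws(df$postcode)
  df$postcode[is.na(df$postcode)] <- ""
  df$registration_start <- parseDateColumn(df$registration_start,
                                           "registration_start", "patient")
  df$registration_end <- parseDateColumn(df$registration_end,
                                         "registration_end", "patient")
  df$death_date <- parseDateColumn(df$death_date, "death_date", "patient")
  validatePatients(df)
}

#' @rdname readPatients
#' @param patients patient data.frame.
#' @export
writePatients <- function(patients, path) {
  df <- validatePatients(patients)
  out <- data.frame(patient_id = df$patient_id,
                    practice_id = df$practice_id,
                    postcode = df$postcode,
                    registration_start = fmtDate(df$registration_start),
                    registration_end = fmtDate(df$registration_end),
                    death_date = fmtDate(df$death_date),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a patient table
#' @param df candidate data.frame.
#' @return the validated data.frame.
#' @export
validatePatients <- function(df) {
  requireColumns(df, c("patient_id", "practice_id", "postcode",
                       "registration_start", "registration_end",
                       "death_date"), "patient")
  if (anyDuplicated(df$patient_id))
    rowStop(which(duplicated(df$patient_id))[1L],
            "duplicate patient_id '%s'",
            df$patient_id[duplicated(df$patient_id)][1L])
  bad <- is.na(df$registration_start)
  if (any(bad)) rowStop(firstBad(bad), "missing registration_start")
  bad <- !is.na(df$registration_end) &
    df$registration_start > df$registration_end
  if (any(bad)) rowStop(firstBad(bad),
                        "registration_start after registration_end")
  bad <- !is.na(df$death_date) & df$death_date < df$registration_start
  if (any(bad)) rowStop(firstBad(bad),
                        "death_date before registration_start")
  df
}

#' Read / write the border-crosser table
#'
#' Postcodes that straddle an output-area or region border, with their
#' candidate areas. Columns: `code`, `candidate_oas` (semicolon-separated
#' oa ids).
#'
#' @param path CSV path.
#' @return data.frame with a character `candidate_oas` column.
#' @export
readBorderCrossers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  requireColumns(df, c("code", "candidate_oas"), "border-crosser")
  bad <- !nzchar(trimws(df$candidate_oas))
  if (any(bad)) rowStop(firstBad(bad), "empty candidate_oas")
  df
}

#' @rdname readBorderCrossers
#' @param crossers border-crosser data.frame.
#' @export
writeBorderCrossers <- function(crossers, path) {
  utils::write.csv(crossers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid
# ---------------------------------------------------------------------------

#' Write a concentration surface as an ESRI ASCII grid
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by row-major values, top (northernmost) row first.
#'
#' @param surface a [ConcentrationSurface-class].
#' @param path output path.
#' @param nodata sentinel written for missing cells (default -9999).
#' @export
writeRaster <- function(surface, path, nodata = -9999) {
  v <- surfaceValues(surface)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", surfaceOrigin(surface)[1]),
    sprintf("yllcorner %.10g", surfaceOrigin(surface)[2]),
    sprintf("cellsize %.10g", surfaceCellSize(surface)),
    sprintf("NODATA_value %.10g", nodata)), con)
  for (i in rev(seq_len(nrow(v)))) {  # north first
    row <- v[i, ]
    row[is.na(row)] <- nodata
    writeLines(paste(formatC(row, format = "g", digits = 12),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path grid file path.
#' @param element element symbol to attach (default `""`).
#' @return a [ConcentrationSurface-class].
#' @export
readRaster <- function(path, element = "") {
  lines <- readLines(path)
  if (length(lines) < 7)
    stop("raster format error: truncated file", call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("raster format error: bad header line ", i, call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr)))
    stop("raster format error: incomplete header", call. = FALSE)
  nc <- hdr$ncols; nr <- hdr$nrows
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop("raster format error: expected ", nr, " data rows, found ",
         length(body), call. = FALSE)
  v <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- suppressWarnings(
      as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row))
      stop("raster format error: row ", i, " has ", length(row),
           " values, expected ", nc, call. = FALSE)
    v[nr - i + 1, ] <- row  # file is north first, matrix is south first
  }
  v[v == hdr$nodata_value] <- NA
  concentrationSurface(v, c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize,
                       element)
}

#' Write / read an exposure table
#'
#' CSV with a `code` column followed by one column per element; missing
#' values are empty cells.
#'
#' @param exposures an [ExposureTable-class].
#' @param path CSV path.
#' @export
writeExposures <- function(exposures, path) {
  m <- exposureMatrix(exposures)
  out <- data.frame(code = rownames(m), stringsAsFactors = FALSE)
  for (el in colnames(m)) {
    col <- formatC(m[, el], format = "g", digits = 12)
    col[is.na(m[, el])] <- ""
    out[[el]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeExposures
#' @return `readExposures()` returns an [ExposureTable-class].
#' @export
readExposures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  requireColumns(df, "code", "exposure")
  elements <- setdiff(names(df), "code")
  m <- matrix(NA_real_, nrow(df), length(elements),
              dimnames = list(df$code, elements))
  for (el in elements) {
    raw <- trimws(df[[el]])
    raw[!nzchar(raw)] <- NA
    m[, el] <- parseNumericColumn(raw, el, "exposure")
  }
  exposureTable(m)
}
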