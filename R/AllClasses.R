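#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib geolink, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# ElementPanel
# ---------------------------------------------------------------------------

#' Panel of soil elements selected for linkage
#'
#' Holds the ordered element symbols carried through the pipeline together
#' with the analytical detection limit of each (mg/kg). The detection limit
#' is what allows below-detection survey values to be carried as flags and
#' the element-exclusion rule to be evaluated without imputation.
#'
#' @slot elements character vector of unique element symbols.
#' @slot detectionLimit numeric vector, same length, strictly positive
#'   detection limit in mg/kg for each element.
#' @export
setClass("ElementPanel",
  representation(elements = "character", detectionLimit = "numeric"),
  validity = function(object) {
    if (length(object@elements) != length(object@detectionLimit))
      return("elements and detectionLimit must have equal length")
    if (anyDuplicated(object@elements))
      return("element symbols must be unique")
    if (any(!is.finite(object@detectionLimit) | object@detectionLimit <= 0))
      return("detection limits must be finite and > 0")
    TRUE
  })

#' Construct an element panel
#'
#' @param elements character vector of element symbols.
#' @param detectionLimit numeric vector of detection limits (mg/kg), in
#'   the same order; a single value is recycled.
#' @return an [ElementPanel-class] object.
#' @examples
#' elementPanel(c("Pb", "Zn"), c(1.3, 5))
#' @export
elementPanel <- function(elements, detectionLimit) {
  if (length(detectionLimit) == 1L)
    detectionLimit <- rep(detectionLimit, length(elements))
  new("ElementPanel", elements = as.character(elements),
      detectionLimit = as.numeric(detectionLimit))
}

#' The default 15-element linkage panel
#'
#' The elements retained for linkage: the major soil elements (Ca, Al, Si),
#' iron for its role in trace-element mobility, and the trace elements of
#' health interest (As, Cr, Cu, Pb, Mn, Ni, P, Se, U, V, Zn). Detection
#' limits are indicative XRFS values in mg/kg.
#'
#' @return an [ElementPanel-class] with 15 entries.
#' @export
defaultElementPanel <- function() {
  elementPanel(
    c("Ca", "Al", "Si", "Fe", "As", "Cr", "Cu", "Pb",
      "Mn", "Ni", "P", "Se", "U", "V", "Zn"),
    c(100, 500, 1000, 100, 0.9, 3, 1.3, 1.3,
      5, 1.3, 50, 0.2, 0.5, 3, 1.3))
}

#' @describeIn ElementPanel-class element symbols, in panel order.
#' @param x an `ElementPanel`.
#' @export
panelElements <- function(x) x@elements

#' @describeIn ElementPanel-class named vector of detection limits (mg/kg).
#' @export
panelDetectionLimits <- function(x) {
  stats::setNames(x@detectionLimit, x@elements)
}

setMethod("show", "ElementPanel", function(object) {
  cat("ElementPanel with", length(object@elements), "elements:",
      paste(object@elements, collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# SoilSurvey (SummarizedExperiment: elements x sites)
# ---------------------------------------------------------------------------

#' Soil geochemistry survey container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with elements as rows and
#' sample sites as columns. Two assays are carried: `concentration`
#' (mg/kg; `NA` where the measurement fell below the detection limit) and
#' `belowDetection` (logical flags). Site coordinates (planar metres,
#' x east / y north) and the sampling stratum (`urban`, `rural`,
#' `background`) live in `colData`; detection limits in `rowData`.
#'
#' @export
setClass("SoilSurvey", contains = "SummarizedExperiment")

validSoilSurvey <- function(object) {
  need <- c("concentration", "belowDetection")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    return("assays 'concentration' and 'belowDetection' are required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("site_id", "x", "y", "source"))
    if (!col %in% colnames(cd)) return(paste0("colData lacks '", col, "'"))
  if (any(!is.finite(cd$x)) || any(!is.finite(cd$y)))
    return("site coordinates must be finite")
  if (!all(cd$source %in% c("urban", "rural", "background")))
    return("source must be one of urban, rural, background")
  if (anyDuplicated(cd$site_id)) return("site_id values must be unique")
  conc <- SummarizedExperiment::assay(object, "concentration")
  if (any(conc < 0, na.rm = TRUE))
    return("concentrations must be >= 0")
  bd <- SummarizedExperiment::assay(object, "belowDetection")
  if (!is.logical(bd)) return("belowDetection assay must be logical")
  if (!"detection_limit" %in%
      colnames(SummarizedExperiment::rowData(object)))
    return("rowData lacks 'detection_limit'")
  TRUE
}
setValidity("SoilSurvey", validSoilSurvey)

#' Construct a soil survey object
#'
#' @param sites data.frame with columns `site_id`, `x`, `y` (metres) and
#'   `source` (one of `"urban"`, `"rural"`, `"background"`).
#' @param concentrations numeric matrix, elements x sites (mg/kg); cells
#'   flagged below detection should be `NA`.
#' @param belowDetection logical matrix of the same shape.
#' @param panel an [ElementPanel-class]; its order defines the row order.
#' @return a [SoilSurvey-class].
#' @export
SoilSurvey <- function(sites, concentrations, belowDetection, panel) {
  elements <- panelElements(panel)
  stopifnot(nrow(concentrations) == length(elements),
            ncol(concentrations) == nrow(sites),
            identical(dim(concentrations), dim(belowDetection)))
  rownames(concentrations) <- elements
  rownames(belowDetection) <- elements
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = concentrations,
                  belowDetection = belowDetection),
    colData = S4Vectors::DataFrame(sites),
    rowData = S4Vectors::DataFrame(
      detection_limit = unname(panelDetectionLimits(panel)),
      row.names = elements))
  new("SoilSurvey", se)
}

#' @describeIn SoilSurvey-class concentration assay (elements x sites).
#' @param x a `SoilSurvey`.
#' @export
concentrations <- function(x) {
  SummarizedExperiment::assay(x, "concentration")
}

#' @describeIn SoilSurvey-class logical below-detection flags.
#' @export
belowDetection <- function(x) {
  SummarizedExperiment::assay(x, "belowDetection")
}

#' @describeIn SoilSurvey-class site table (data.frame).
#' @export
siteInfo <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn SoilSurvey-class the [ElementPanel-class] of the survey.
#' @export
surveyPanel <- function(x) {
  elementPanel(rownames(x),
               SummarizedExperiment::rowData(x)$detection_limit)
}

#' Concentrations as used for interpolation
#'
#' Below-detection measurements contribute at half the detection limit, the
#' conventional substitution for left-censored geochemical data; retained
#' elements typically have few such samples (elements dominated by censored
#' values are removed beforehand by [lodExclusion()]).
#'
#' @param survey a [SoilSurvey-class].
#' @param element element symbol.
#' @return numeric vector, one value per site, no `NA`s.
#' @export
interpolationValues <- function(survey, element) {
  if (!element %in% rownames(survey))
    stop("element '", element, "' is not in the survey", call. = FALSE)
  z <- concentrations(survey)[element, ]
  bd <- belowDetection(survey)[element, ]
  lod <- panelDetectionLimits(surveyPanel(survey))[[element]]
  z[bd] <- lod / 2
  if (anyNA(z))
    stop("element '", element, "' has unmeasured, unflagged sites",
         call. = FALSE)
  unname(z)
}

# ---------------------------------------------------------------------------
# ConcentrationSurface
# ---------------------------------------------------------------------------

#' Regular raster of interpolated concentrations for one element
#'
#' Cells are half-open squares; cell `(i, j)` (row i from the south, column
#' j from the west, 1-based) covers
#' `[x0 + (j-1) c, x0 + j c) x [y0 + (i-1) c, y0 + i c)` where `c` is the
#' cell size and `(x0, y0)` the lower-left corner. Cells with no survey
#' data inside the interpolation search radius are `NA`.
#'
#' @slot element element symbol.
#' @slot origin numeric of length 2, lower-left corner `(x0, y0)` (metres).
#' @slot cellSize cell side in metres.
#' @slot values numeric matrix `n_rows x n_cols`, row 1 = southernmost.
#' @export
setClass("ConcentrationSurface",
  representation(element = "character", origin = "numeric",
                 cellSize = "numeric", values = "matrix"),
  validity = function(object) {
    if (length(object@origin) != 2 || any(!is.finite(object@origin)))
      return("origin must be two finite coordinates")
    if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      return("cellSize must be a single positive number")
    if (any(object@values < 0, na.rm = TRUE))
      return("non-missing cells must be >= 0")
    TRUE
  })

#' Construct a concentration surface
#'
#' @param values numeric matrix (rows south to north).
#' @param origin lower-left corner `(x0, y0)` in metres.
#' @param cellSize cell side in metres (default 1000).
#' @param element element symbol (default `""`).
#' @return a [ConcentrationSurface-class].
#' @export
concentrationSurface <- function(values, origin, cellSize = 1000,
                                 element = "") {
  new("ConcentrationSurface", element = element,
      origin = as.numeric(origin), cellSize = as.numeric(cellSize),
      values = values)
}

#' @describeIn ConcentrationSurface-class cell values matrix (row 1 south).
#' @param x a `ConcentrationSurface`.
#' @export
surfaceValues <- function(x) x@values

#' @describeIn ConcentrationSurface-class `(x0, y0)` lower-left corner.
#' @export
surfaceOrigin <- function(x) x@origin

#' @describeIn ConcentrationSurface-class cell side (metres).
#' @export
surfaceCellSize <- function(x) x@cellSize

#' @describeIn ConcentrationSurface-class element symbol.
#' @export
surfaceElement <- function(x) x@element

#' @describeIn ConcentrationSurface-class extent
#'   `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
surfaceExtent <- function(x) {
  d <- dim(x@values)
  c(x@origin[1], x@origin[1] + d[2] * x@cellSize,
    x@origin[2], x@origin[2] + d[1] * x@cellSize)
}

setMethod("show", "ConcentrationSurface", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ConcentrationSurface '%s': %d rows x %d cols, cell %g m, origin (%g, %g)\n",
    object@element, d[1], d[2], object@cellSize,
    object@origin[1], object@origin[2]))
  cat(sprintf("  %d of %d cells missing\n",
              sum(is.na(object@values)), length(object@values)))
})

# ---------------------------------------------------------------------------
# ExposureTable
# ---------------------------------------------------------------------------

#' Per-postcode, per-element exposure lookup table
#'
#' The linkage key: one row per postcode, one column per element, `NA`
#' where the postcode centroid fell outside interpolation coverage.
#'
#' @slot values numeric matrix, postcode codes as rownames, element symbols
#'   as colnames.
#' @export
setClass("ExposureTable",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
      return("values must carry postcode rownames and element colnames")
    if (anyDuplicated(rownames(v)))
      return("postcode codes must be unique")
    if (any(v < 0, na.rm = TRUE))
      return("exposure values must be >= 0 or missing")
    TRUE
  })

#' Construct an exposure table
#'
#' @param values numeric matrix with postcode rownames and element colnames.
#' @return an [ExposureTable-class].
#' @export
exposureTable <- function(values) new("ExposureTable", values = values)

#' @describeIn ExposureTable-class the underlying matrix.
#' @param x an `ExposureTable`.
#' @export
exposureMatrix <- function(x) x@values

#' @describeIn ExposureTable-class postcode codes.
#' @export
exposureCodes <- function(x) rownames(x@values)

#' @describeIn ExposureTable-class element symbols.
#' @export
exposureElements <- function(x) colnames(x@values)

setMethod("show", "ExposureTable", function(object) {
  v <- object@values
  cat(sprintf("ExposureTable: %d postcodes x %d elements (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
})

# ---------------------------------------------------------------------------
# IdwConfig
# ---------------------------------------------------------------------------

#' Interpolation settings
#'
#' @slot radius search radius in metres (default 5000): sites farther than
#'   this contribute nothing, and a query with no site inside the radius is
#'   returned as missing.
#' @slot power inverse-distance exponent p (default 2).
#' @slot cellSize raster cell side in metres (default 1000).
#' @slot coincidenceEpsilon distance (metres, default 1) under which a site
#'   is treated as coincident with the query; coincident site values are
#'   averaged arithmetically, avoiding the d = 0 singularity.
#' @export
setClass("IdwConfig",
  representation(radius = "numeric", power = "numeric",
                 cellSize = "numeric", coincidenceEpsilon = "numeric"),
  validity = function(object) {
    for (s in c("radius", "power", "cellSize", "coincidenceEpsilon")) {
      v <- slot(object, s)
      if (length(v) != 1 || !is.finite(v))
        return(paste(s, "must be a single finite number"))
    }
    if (object@radius <= 0) return("radius must be > 0")
    if (object@power <= 0) return("power must be > 0")
    if (object@cellSize <= 0) return("cellSize must be > 0")
    if (object@coincidenceEpsilon < 0)
      return("coincidenceEpsilon must be >= 0")
    TRUE
  })

#' Construct interpolation settings
#'
#' @param radius search radius, metres.
#' @param power inverse-distance exponent.
#' @param cellSize raster cell side, metres.
#' @param coincidenceEpsilon coincidence distance, metres.
#' @return an [IdwConfig-class].
#' @examples
#' idwConfig()                 # 5 km radius, 1 km cells, p = 2
#' idwConfig(power = 50)       # effectively nearest-neighbour
#' @export
idwConfig <- function(radius = 5000, power = 2, cellSize = 1000,
                      coincidenceEpsilon = 1) {
  new("IdwConfig", radius = radius, power = power, cellSize = cellSize,
      coincidenceEpsilon = coincidenceEpsilon)
}

setMethod("show", "IdwConfig", function(object) {
  cat(sprintf("IdwConfig: radius %g m, power %g, cell %g m, epsilon %g m\n",
              object@radius, object@power, object@cellSize,
              object@coincidenceEpsilon))
})
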