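# Radius-limited inverse distance weighting. The kernel lives in
# src/spatial.cpp behind a uniform grid-bucket index; results are exact
# (identical to naive all-pairs evaluation) because every site within the
# search radius of a query lies in the 3x3 bucket neighbourhood when the
# bucket side equals the radius.

#' Inverse-distance-weighted estimates at query points
#'
#' For each query point, sites within `radius` contribute with weight
#' `d^-power`; queries with no site inside the radius return `NA`
#' (missing, not zero). Sites within `coincidenceEpsilon` of the query are
#' averaged arithmetically instead, which both resolves the `d = 0`
#' singularity and makes the interpolator exact at site locations.
#'
#' @param x,y site coordinates (metres).
#' @param values site values (finite, `>= 0`).
#' @param qx,qy query coordinates.
#' @param config an [IdwConfig-class].
#' @return numeric vector of estimates, `NA` where out of coverage. Each
#'   non-missing estimate lies within the range of its contributing values.
#' @examples
#' # two sites at 1 km (z = 10) and 2 km (z = 40) from origin, p = 2
#' idwAtPoints(c(1000, 2000), c(0, 0), c(10, 40), 0, 0, idwConfig())
#' @export
idwAtPoints <- function(x, y, values, qx, qy, config = idwConfig()) {
  validObject(config)
  stopifnot(length(x) == length(y), length(x) == length(values))
  if (length(values) > 0) {
    if (any(!is.finite(values))) stop("site values must be finite",
                                      call. = FALSE)
    if (any(values < 0)) stop("site values must be >= 0", call. = FALSE)
    if (any(!is.finite(x)) || any(!is.finite(y)))
      stop("site coordinates must be finite", call. = FALSE)
  }
  cpp_idw(as.numeric(x), as.numeric(y), as.numeric(values),
          as.numeric(qx), as.numeric(qy),
          config@radius, config@power, config@coincidenceEpsilon)
}

#' Build a concentration raster by IDW
#'
#' Evaluates [idwAtPoints()] at every cell centre of a regular grid
#' covering `extent`. The grid has `ceiling(width / cellSize)` columns and
#' `ceiling(height / cellSize)` rows anchored at the extent's lower-left
#' corner. An empty site list yields an all-missing surface.
#'
#' @param x,y,values site coordinates and values.
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres, non-degenerate.
#' @param config an [IdwConfig-class].
#' @param element element symbol to attach.
#' @return a [ConcentrationSurface-class].
#' @export
buildSurface <- function(x, y, values, extent, config = idwConfig(),
                         element = "") {
  stopifnot(length(extent) == 4)
  if (!(extent[2] > extent[1] && extent[4] > extent[3]))
    stop("extent is degenerate", call. = FALSE)
  cs <- config@cellSize
  nCols <- as.integer(ceiling((extent[2] - extent[1]) / cs - 1e-9))
  nRows <- as.integer(ceiling((extent[4] - extent[3]) / cs - 1e-9))
  cx <- extent[1] + (seq_len(nCols) - 0.5) * cs
  cy <- extent[3] + (seq_len(nRows) - 0.5) * cs
  qx <- rep(cx, times = nRows)
  qy <- rep(cy, each = nCols)
  est <- idwAtPoints(x, y, values, qx, qy, config)
  v <- matrix(est, nrow = nRows, ncol = nCols, byrow = TRUE)
  concentrationSurface(v, c(extent[1], extent[3]), cs, element)
}

#' Build one surface per retained element from a survey
#'
#' Convenience wrapper over [buildSurface()]: below-detection samples
#' contribute at half the detection limit (see [interpolationValues()]).
#'
#' @param survey a [SoilSurvey-class].
#' @param elements element symbols (default: all survey elements).
#' @param extent `c(xmin, xmax, ymin, ymax)`; default: the site bounding
#'   box padded to whole cells.
#' @param config an [IdwConfig-class].
#' @return named list of [ConcentrationSurface-class], one per element.
#' @export
surfacesFromSurvey <- function(survey, elements = rownames(survey),
                               extent = NULL, config = idwConfig()) {
  sites <- siteInfo(survey)
  if (is.null(extent)) {
    cs <- config@cellSize
    extent <- c(floor(min(sites$x) / cs) * cs,
                ceiling(max(sites$x) / cs) * cs,
                floor(min(sites$y) / cs) * cs,
                ceiling(max(sites$y) / cs) * cs)
  }
  out <- lapply(elements, function(el) {
    buildSurface(sites$x, sites$y, interpolationValues(survey, el),
                 extent, config, element = el)
  })
  stats::setNames(out, elements)
}

#' Raster value at point locations
#'
#' Returns the value of the half-open cell containing each point: a point
#' exactly on a shared vertical edge belongs to the cell to its east, and
#' on a shared horizontal edge to the cell to its north. Points outside
#' the raster extent (including on the top/right boundary) are missing.
#'
#' @param surface a [ConcentrationSurface-class].
#' @param x,y point coordinates (metres).
#' @return numeric vector of cell values (`NA` = missing / out of extent).
#' @export
valueAtCentroid <- function(surface, x, y) {
  v <- surfaceValues(surface)
  o <- surfaceOrigin(surface)
  cs <- surfaceCellSize(surface)
  j <- floor((x - o[1]) / cs) + 1
  i <- floor((y - o[2]) / cs) + 1
  ok <- i >= 1 & i <= nrow(v) & j >= 1 & j <= ncol(v)
  out <- rep(NA_real_, length(x))
  out[ok] <- v[cbind(i[ok], j[ok])]
  out
}

#' Nearest-site distances and their quantile summary
#'
#' Exact Euclidean distance from each centroid to its nearest survey site
#' (grid-indexed expanding-ring search), with the quantiles used to judge
#' whether centroid-point exposure assignment is appropriate for the
#' sampling density at hand.
#'
#' @param cx,cy centroid coordinates (metres).
#' @param sx,sy site coordinates; must be non-empty.
#' @param probs quantile probabilities (default `c(0.5, 0.97)`).
#' @return list with `distances` (metres, one per centroid) and
#'   `quantiles` (named numeric).
#' @export
nearestSiteDistances <- function(cx, cy, sx, sy, probs = c(0.5, 0.97)) {
  if (length(sx) == 0) stop("no survey sites: no coverage at all",
                            call. = FALSE)
  stopifnot(length(sx) == length(sy), length(cx) == length(cy))
  d <- cpp_nn_dist(as.numeric(cx), as.numeric(cy),
                   as.numeric(sx), as.numeric(sy))
  list(distances = d,
       quantiles = stats::quantile(d, probs = probs, names = TRUE))
}
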