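#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

setOldClass(c("POSIXct", "POSIXt"))

## ---- acoustic containers ---------------------------------------------------

#' One site's raw sound level series
#'
#' Holds a logger's 1-second A-weighted equivalent sound levels (LAeq,1s)
#' together with their timestamps. Timestamps are local civil time stored as
#' POSIXct in the "UTC" zone (no daylight-saving transitions are modelled);
#' they must be strictly increasing and levels must lie in [0, 140] dB(A).
#'
#' @slot siteId single site identifier.
#' @slot time POSIXct vector, strictly increasing, 1-s resolution.
#' @slot level numeric vector of dB(A) values, same length as \code{time}.
#' @slot metadata free-form list (the synthetic generator records injected
#'   spike times and gaps here).
#' @exportClass SoundLevelSeries
setClass("SoundLevelSeries",
  slots = c(siteId = "character", time = "POSIXct", level = "numeric",
            metadata = "list"))

setValidity("SoundLevelSeries", function(object) {
  msg <- character()
  if (length(object@siteId) != 1L || is.na(object@siteId))
    msg <- c(msg, "siteId must be a single non-NA string")
  if (length(object@time) != length(object@level))
    msg <- c(msg, "time and level must have the same length")
  if (length(object@time) > 1L) {
    dt <- diff(as.numeric(object@time))
    if (any(dt <= 0))
      msg <- c(msg, "timestamps must be strictly increasing (no duplicates)")
  }
  lv <- object@level
  if (length(lv) && (any(!is.finite(lv)) || any(lv < 0) || any(lv > 140)))
    msg <- c(msg, "levels must be finite and within [0, 140] dB(A)")
  if (length(msg)) msg else TRUE
})

#' Construct a SoundLevelSeries
#'
#' @param siteId site identifier.
#' @param time POSIXct timestamps (strictly increasing, 1-s resolution).
#' @param level dB(A) levels, same length as \code{time}.
#' @param metadata optional list of provenance information.
#' @return A \linkS4class{SoundLevelSeries}.
#' @examples
#' w <- analysisWindow()
#' s <- soundLevelSeries("S1", windowStart(w) + 0:9, rep(60, 10))
#' nSamples(s)
#' @export
soundLevelSeries <- function(siteId, time, level, metadata = list()) {
  if (!inherits(time, "POSIXct"))
    stop("time must be POSIXct")
  o <- order(as.numeric(time))
  if (is.unsorted(as.numeric(time)))
    stop("timestamps must be supplied in increasing order")
  new("SoundLevelSeries", siteId = as.character(siteId), time = time,
      level = as.numeric(level), metadata = metadata)
}

#' Five-day analysis window
#'
#' The fixed measurement window used throughout: 120 hours from a Wednesday
#' at 06:00 local time to the following Monday at 06:00, i.e. 432,000
#' expected one-second samples.
#'
#' @slot start,end POSIXct window bounds (half-open: samples with
#'   \code{start <= t < end} belong to the window).
#' @slot expectedSeconds number of 1-s samples a complete series holds.
#' @exportClass AnalysisWindow
setClass("AnalysisWindow",
  slots = c(start = "POSIXct", end = "POSIXct", expectedSeconds = "numeric"))

setValidity("AnalysisWindow", function(object) {
  dur <- as.numeric(object@end) - as.numeric(object@start)
  if (abs(dur - object@expectedSeconds) > 1e-6)
    return("expectedSeconds must equal the window duration in seconds")
  if (dur <= 0) return("end must come after start")
  TRUE
})

#' Construct the five-day analysis window
#'
#' @param start POSIXct start of the window; defaults to Wednesday
#'   2015-11-11 06:00, a Wednesday within the measurement campaign season.
#'   The window always spans 120 hours (Wednesday 06:00 to Monday 06:00).
#' @return An \linkS4class{AnalysisWindow}.
#' @export
analysisWindow <- function(start = as.POSIXct("2015-11-11 06:00:00", tz = "UTC")) {
  if (!inherits(start, "POSIXct")) start <- as.POSIXct(start, tz = "UTC")
  end <- start + 120 * 3600
  new("AnalysisWindow", start = start, end = end, expectedSeconds = 432000)
}

#' @rdname analysisWindow
#' @param window an \linkS4class{AnalysisWindow}.
#' @export
windowStart <- function(window) window@start

#' @rdname analysisWindow
#' @export
windowEnd <- function(window) window@end

#' @rdname analysisWindow
#' @export
expectedSeconds <- function(window) window@expectedSeconds

#' Cleaning report for one series
#'
#' Records the completeness and outlier-removal bookkeeping for a site:
#' how many 1-s samples were expected and present, the missing fraction,
#' the mean and SD of the dB values used by the 3-SD outlier rule, the
#' number of samples removed, and whether the site passes the 10%
#' missingness rule (more than 10% missing excludes; exactly 10% is kept).
#'
#' Fields not yet determined at a given cleaning stage are NA.
#'
#' @exportClass CleaningReport
setClass("CleaningReport",
  slots = c(nExpected = "numeric", nPresent = "numeric",
            fractionMissing = "numeric", meanDb = "numeric", sdDb = "numeric",
            nOutliersRemoved = "numeric", valid = "logical"))

setValidity("CleaningReport", function(object) {
  msg <- character()
  if (!is.na(object@nExpected) && !is.na(object@nPresent)) {
    f <- 1 - object@nPresent / object@nExpected
    if (!is.na(object@fractionMissing) && abs(f - object@fractionMissing) > 1e-9)
      msg <- c(msg, "fractionMissing must equal 1 - nPresent/nExpected")
  }
  if (!is.na(object@nOutliersRemoved) && !is.na(object@nPresent) &&
      object@nOutliersRemoved > object@nPresent)
    msg <- c(msg, "cannot remove more outliers than samples present")
  if (length(msg)) msg else TRUE
})

.cleaningReport <- function(nExpected = NA_real_, nPresent = NA_real_,
                           fractionMissing = NA_real_, meanDb = NA_real_,
                           sdDb = NA_real_, nOutliersRemoved = NA_real_,
                           valid = NA) {
  new("CleaningReport", nExpected = nExpected, nPresent = nPresent,
      fractionMissing = fractionMissing, meanDb = meanDb, sdDb = sdDb,
      nOutliersRemoved = nOutliersRemoved, valid = valid)
}

#' Aggregated noise metrics for one site
#'
#' The five period levels computed from a cleaned series: Lday (06-18),
#' Levening (18-22), Lnight (22-06), LAeq24h (the full 06-06 cycle) and
#' Lden (duration-weighted with +5 dB on evening and +10 dB on night
#' energy). All values in dB(A).
#'
#' @exportClass NoiseMetrics
setClass("NoiseMetrics",
  slots = c(siteId = "character", lDay = "numeric", lEvening = "numeric",
            lNight = "numeric", lAeq24h = "numeric", lDen = "numeric",
            report = "CleaningReport"))

setValidity("NoiseMetrics", function(object) {
  msg <- character()
  tol <- 1e-6
  v <- c(object@lDay, object@lEvening, object@lNight, object@lAeq24h,
         object@lDen)
  if (any(!is.finite(v))) return("all metrics must be finite")
  if (object@lDen < object@lAeq24h - tol ||
      object@lDen > object@lAeq24h + 10 + tol)
    msg <- c(msg, "lDen must lie within [lAeq24h, lAeq24h + 10]")
  per <- c(object@lDay, object@lEvening, object@lNight)
  if (object@lAeq24h < min(per) - tol || object@lAeq24h > max(per) + tol)
    msg <- c(msg, "lAeq24h must lie between the period level extremes")
  if (length(msg)) msg else TRUE
})

## ---- GIS layers ------------------------------------------------------------

#' Road network layer
#'
#' Polylines in a projected metric coordinate system, each carrying one of
#' the four road classes: \code{large} (national roads / highways),
#' \code{medium} (metropolitan, provincial and regional roads), \code{small}
#' (local roads) and \code{very_small} (neighbourhood roads).
#'
#' @slot coords list of two-column (x, y) matrices, one polyline each.
#' @slot roadClass character vector parallel to \code{coords}.
#' @exportClass RoadNetwork
setClass("RoadNetwork", slots = c(coords = "list", roadClass = "character"))

.ROAD_CLASSES <- c("large", "medium", "small", "very_small")

setValidity("RoadNetwork", function(object) {
  msg <- character()
  if (length(object@coords) != length(object@roadClass))
    msg <- c(msg, "one road class per polyline required")
  if (length(object@roadClass) && !all(object@roadClass %in% .ROAD_CLASSES))
    msg <- c(msg, sprintf("road classes must be among: %s",
                          paste(.ROAD_CLASSES, collapse = ", ")))
  for (m in object@coords) {
    if (!is.matrix(m) || ncol(m) != 2 || nrow(m) < 2 || any(!is.finite(m))) {
      msg <- c(msg, "each polyline must be a finite 2-column matrix with >= 2 vertices")
      break
    }
    if (sum(sqrt(rowSums(diff(m)^2))) <= 0) {
      msg <- c(msg, "degenerate polyline of zero length")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RoadNetwork-class
#' @param coords list of 2-column coordinate matrices (one per polyline).
#' @param roadClass road class per polyline.
#' @return A \linkS4class{RoadNetwork}.
#' @export
roadNetwork <- function(coords = list(), roadClass = character()) {
  new("RoadNetwork", coords = coords, roadClass = as.character(roadClass))
}

#' Point feature layer
#'
#' Projected point locations of one feature category (airport, railway
#' track in activity, any railway track, church, police station, hospital).
#'
#' @slot category single category label.
#' @slot coords n x 2 matrix of projected coordinates in metres.
#' @exportClass PointFeatureSet
setClass("PointFeatureSet", slots = c(category = "character", coords = "matrix"))

.POINT_CATEGORIES <- c("airport", "railway_active", "railway_any", "church",
                       "police", "hospital")

setValidity("PointFeatureSet", function(object) {
  if (length(object@category) != 1L)
    return("category must be a single label")
  if (nrow(object@coords) && (ncol(object@coords) != 2 ||
                              any(!is.finite(object@coords))))
    return("coords must be a finite n x 2 matrix")
  TRUE
})

#' @rdname PointFeatureSet-class
#' @param category feature category label.
#' @param coords n x 2 coordinate matrix.
#' @return A \linkS4class{PointFeatureSet}.
#' @export
pointFeatureSet <- function(category, coords = matrix(numeric(), ncol = 2)) {
  coords <- as.matrix(coords)
  if (length(coords) == 0) coords <- matrix(numeric(), ncol = 2)
  new("PointFeatureSet", category = as.character(category), coords = coords)
}

#' Land-use polygon layer
#'
#' Simple (non-self-intersecting) polygons in projected metric coordinates,
#' each labelled with one of the five land-use classes: residential,
#' commercial, industrial, buildings, nature.
#'
#' @slot polygons list of two-column vertex matrices (rings; first vertex
#'   need not be repeated at the end).
#' @slot useClass character vector parallel to \code{polygons}.
#' @exportClass LandUseLayer
setClass("LandUseLayer", slots = c(polygons = "list", useClass = "character"))

.LANDUSE_CLASSES <- c("residential", "commercial", "industrial", "buildings",
                      "nature")

setValidity("LandUseLayer", function(object) {
  msg <- character()
  if (length(object@polygons) != length(object@useClass))
    msg <- c(msg, "one use class per polygon required")
  if (length(object@useClass) && !all(object@useClass %in% .LANDUSE_CLASSES))
    msg <- c(msg, sprintf("use classes must be among: %s",
                          paste(.LANDUSE_CLASSES, collapse = ", ")))
  for (p in object@polygons)
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p))) {
      msg <- c(msg, "each polygon must be a finite 2-column matrix with >= 3 vertices")
      break
    }
  if (length(msg)) msg else TRUE
})

#' @rdname LandUseLayer-class
#' @param polygons list of 2-column vertex matrices.
#' @param useClass land-use class per polygon.
#' @return A \linkS4class{LandUseLayer}.
#' @export
landUseLayer <- function(polygons = list(), useClass = character()) {
  new("LandUseLayer", polygons = polygons, useClass = as.character(useClass))
}

#' Household point layer
#'
#' One projected point per household.
#'
#' @slot coords n x 2 matrix of projected coordinates in metres.
#' @exportClass HouseholdLayer
setClass("HouseholdLayer", slots = c(coords = "matrix"))

setValidity("HouseholdLayer", function(object) {
  if (nrow(object@coords) && (ncol(object@coords) != 2 ||
                              any(!is.finite(object@coords))))
    return("coords must be a finite n x 2 matrix")
  TRUE
})

#' @rdname HouseholdLayer-class
#' @param coords n x 2 coordinate matrix.
#' @return A \linkS4class{HouseholdLayer}.
#' @export
householdLayer <- function(coords = matrix(numeric(), ncol = 2)) {
  coords <- as.matrix(coords)
  if (length(coords) == 0) coords <- matrix(numeric(), ncol = 2)
  new("HouseholdLayer", coords = coords)
}

#' Vegetation-index raster
#'
#' A regular grid of normalized difference vegetation index (NDVI) values
#' in [-1, 1] (NA allowed for missing cells). \code{values[i, j]} is the
#' cell whose centre is at \code{(xll + (j - 0.5) * cellSize,
#' yll + (i - 0.5) * cellSize)}: row index increases northwards.
#'
#' @slot xll,yll coordinates of the lower-left corner of the grid, metres.
#' @slot cellSize cell edge length in metres.
#' @slot values numeric matrix of index values.
#' @exportClass RasterGrid
setClass("RasterGrid",
  slots = c(xll = "numeric", yll = "numeric", cellSize = "numeric",
            values = "matrix"))

setValidity("RasterGrid", function(object) {
  if (object@cellSize <= 0) return("cellSize must be positive")
  v <- object@values
  if (any(v < -1 | v > 1, na.rm = TRUE))
    return("raster values must lie in [-1, 1] (or NA)")
  TRUE
})

#' @rdname RasterGrid-class
#' @param xll,yll lower-left corner coordinates.
#' @param cellSize cell edge length in metres.
#' @param values matrix of values (row 1 is the southernmost row).
#' @return A \linkS4class{RasterGrid}.
#' @export
rasterGrid <- function(xll, yll, cellSize, values) {
  new("RasterGrid", xll = xll, yll = yll, cellSize = cellSize,
      values = as.matrix(values))
}

## ---- feature matrix --------------------------------------------------------

#' Sites-by-predictors feature matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"features"} assay
#' holds candidate predictors (rows) by monitoring sites (columns).
#' \code{rowData} carries the variable metadata (category, variable type,
#' buffer radius, expected sign, unit); \code{colData} carries the site
#' coordinates and area labels.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  a <- SummarizedExperiment::assay(object, "features")
  if (any(!is.finite(a)))
    msg <- c(msg, "feature values must be finite (no missing values)")
  need <- c("category", "var_type", "buffer_m", "expected_sign", "unit")
  if (!all(need %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, sprintf("rowData must contain: %s",
                          paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values variables x sites numeric matrix.
#' @param variables data.frame of variable metadata with columns
#'   \code{name}, \code{category}, \code{var_type}, \code{buffer_m},
#'   \code{expected_sign}, \code{unit}; one row per row of \code{values}.
#' @param sites data.frame with columns \code{site_id}, \code{x}, \code{y},
#'   \code{area}; one row per column of \code{values}.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
featureMatrix <- function(values, variables, sites) {
  values <- as.matrix(values)
  rownames(values) <- variables$name
  colnames(values) <- sites$site_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    rowData = S4Vectors::DataFrame(variables, row.names = variables$name),
    colData = S4Vectors::DataFrame(sites, row.names = sites$site_id))
  new("FeatureMatrix", se)
}

## ---- model objects ---------------------------------------------------------

#' Ordinary least squares fit summary
#'
#' Minimal container for an intercept OLS fit of noise level on selected
#' predictors: coefficients (named, first element the intercept), standard
#' errors, two-sided t-test p-values, R-squared and adjusted R-squared,
#' fitted values and residuals.
#'
#' @exportClass RegressionFit
setClass("RegressionFit",
  slots = c(variables = "character", coefficients = "numeric", se = "numeric",
            pValues = "numeric", r2 = "numeric", adjR2 = "numeric",
            fitted = "numeric", residuals = "numeric", n = "integer"))

setValidity("RegressionFit", function(object) {
  msg <- character()
  if (object@adjR2 > object@r2 + 1e-9)
    msg <- c(msg, "adjusted R2 cannot exceed R2")
  if (length(object@residuals) &&
      abs(mean(object@residuals)) > 1e-6 * (1 + stats::sd(object@residuals)))
    msg <- c(msg, "residuals of an intercept model must sum to zero")
  if (length(msg)) msg else TRUE
})

#' Fitted land use regression model
#'
#' The end product of the supervised selection procedure: the final OLS fit,
#' the complete selection trace (screening, buffer choice, forward,
#' backward, challenge and augmentation events with the adjusted R-squared
#' before and after each), the thresholds used, and the metadata of the
#' selected variables.
#'
#' @exportClass LURModel
setClass("LURModel",
  slots = c(fit = "RegressionFit", trace = "data.frame", config = "list",
            variableData = "DataFrame"))

#' Prediction-evaluation report
#'
#' Measured-versus-predicted diagnostics: overall and per-area squared
#' Pearson correlation, residuals and fitted values, a descriptive
#' Shapiro-Wilk normality statistic for the standardized residuals, and
#' binned level distributions (proportions) for the measured and predicted
#' values.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  slots = c(r2Overall = "numeric", r2ByArea = "numeric", residuals = "numeric",
            predicted = "numeric", measured = "numeric", normality = "list",
            histMeasured = "numeric", histPredicted = "numeric",
            binWidth = "numeric"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  r2 <- c(object@r2Overall, object@r2ByArea)
  r2 <- r2[!is.na(r2)]
  if (any(r2 < -1e-9 | r2 > 1 + 1e-9))
    msg <- c(msg, "R2 values must lie in [0, 1]")
  for (h in list(object@histMeasured, object@histPredicted))
    if (length(h) && abs(sum(h) - 1) > 1e-9)
      msg <- c(msg, "histogram proportions must sum to 1")
  if (length(msg)) msg else TRUE
})
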