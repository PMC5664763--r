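#' @include AllClasses.R
NULL

# All vector layers live in a projected metric CRS. Coordinates that all
# fit inside [-180, 180] x [-90, 90] are almost certainly geographic
# (lon/lat) and are refused: buffers in metres are meaningless on degrees.
.checkProjected <- function(xy, what) {
  if (nrow(xy) == 0L) return(invisible())
  if (all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90))
    stop(sprintf(paste0("%s coordinates look geographic (lon/lat); ",
                        "re-project to a metric CRS before ingestion"), what))
  invisible()
}

.tsFormat <- "%Y-%m-%dT%H:%M:%S"

#' Read a per-site 1-second level series CSV
#'
#' Expects a header \code{timestamp,laeq_db} with one row per second,
#' timestamps ISO-8601 to the second (local civil time; read as UTC, no
#' daylight-saving handling).
#'
#' @param path CSV file path.
#' @param siteId site identifier; defaults to the file name without
#'   extension.
#' @return A \linkS4class{SoundLevelSeries}.
#' @export
readLevelSeries <- function(path, siteId = NULL) {
  if (is.null(siteId))
    siteId <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, colClasses = list(character = "timestamp"))
  if (!all(c("timestamp", "laeq_db") %in% names(dt)))
    stop("series CSV must have columns: timestamp, laeq_db")
  tm <- as.POSIXct(dt$timestamp, format = .tsFormat, tz = "UTC")
  if (anyNA(tm))
    tm <- as.POSIXct(dt$timestamp, tz = "UTC")
  if (anyNA(tm)) stop("unparseable timestamps in ", path)
  if (anyDuplicated(as.numeric(tm)))
    stop("duplicate timestamps in ", path)
  soundLevelSeries(siteId, tm, dt$laeq_db)
}

#' @rdname readLevelSeries
#' @param series a \linkS4class{SoundLevelSeries} to write.
#' @export
writeLevelSeries <- function(series, path) {
  data.table::fwrite(data.table::data.table(
    timestamp = format(series@time, .tsFormat, tz = "UTC"),
    laeq_db = series@level), path)
  invisible(path)
}

#' Read or write the site table
#'
#' CSV with columns \code{site_id,x,y,area}; coordinates projected, metres.
#'
#' @param path CSV file path.
#' @return data.frame of sites.
#' @export
readSites <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "x", "y") %in% names(s)))
  .checkProjected(cbind(s$x, s$y), "site")
  if (!"area" %in% names(s)) s$area <- NA_character_
  s$site_id <- as.character(s$site_id)
  s
}

#' @rdname readSites
#' @param sites data.frame of sites to write.
#' @export
writeSites <- function(sites, path) {
  utils::write.csv(sites[, c("site_id", "x", "y", "area")], path,
                   row.names = FALSE)
  invisible(path)
}

## ---- GeoJSON ---------------------------------------------------------------

.geojsonWrite <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.geojsonRead <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(g$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", path)
  g$features
}

.coordsToMatrix <- function(cc)
  do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))

#' Road network GeoJSON I/O
#'
#' Roads are LineString features with the class in property
#' \code{road_class}.
#'
#' @param network a \linkS4class{RoadNetwork}.
#' @param path file path.
#' @return \code{readRoadsGeoJSON} returns a \linkS4class{RoadNetwork}.
#' @export
writeRoadsGeoJSON <- function(network, path) {
  feats <- lapply(seq_along(network@coords), function(i) {
    m <- network@coords[[i]]
    list(type = "Feature",
         properties = list(road_class = network@roadClass[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(r) as.numeric(m[r, ]))))
  })
  .geojsonWrite(feats, path)
}

#' @rdname writeRoadsGeoJSON
#' @export
readRoadsGeoJSON <- function(path) {
  feats <- .geojsonRead(path)
  coords <- list(); cls <- character()
  for (f in feats) {
    if (!identical(f$geometry$type, "LineString"))
      stop("road features must be LineStrings")
    m <- .coordsToMatrix(f$geometry$coordinates)
    .checkProjected(m, "road")
    coords[[length(coords) + 1L]] <- m
    cls <- c(cls, f$properties$road_class)
  }
  roadNetwork(coords, cls)
}

#' Point feature GeoJSON I/O
#'
#' Point features carry their category in property \code{category}; one
#' file may mix categories.
#'
#' @param points named list of \linkS4class{PointFeatureSet} objects.
#' @param path file path.
#' @return \code{readPointsGeoJSON} returns a named list of
#'   \linkS4class{PointFeatureSet} objects keyed by category.
#' @export
writePointsGeoJSON <- function(points, path) {
  feats <- list()
  for (pf in points) {
    for (i in seq_len(nrow(pf@coords)))
      feats[[length(feats) + 1L]] <- list(
        type = "Feature", properties = list(category = pf@category),
        geometry = list(type = "Point",
                        coordinates = as.numeric(pf@coords[i, ])))
  }
  .geojsonWrite(feats, path)
}

#' @rdname writePointsGeoJSON
#' @export
readPointsGeoJSON <- function(path) {
  feats <- .geojsonRead(path)
  cats <- vapply(feats, function(f) f$properties$category, character(1))
  xy <- .coordsToMatrix(lapply(feats, function(f) f$geometry$coordinates))
  .checkProjected(xy, "point feature")
  out <- list()
  for (cat in unique(cats))
    out[[cat]] <- pointFeatureSet(cat, xy[cats == cat, , drop = FALSE])
  out
}

#' Land-use polygon GeoJSON I/O
#'
#' Polygon features (outer ring only) with the class in property
#' \code{use_class}.
#'
#' @param layer a \linkS4class{LandUseLayer}.
#' @param path file path.
#' @return \code{readLandUseGeoJSON} returns a \linkS4class{LandUseLayer}.
#' @export
writeLandUseGeoJSON <- function(layer, path) {
  feats <- lapply(seq_along(layer@polygons), function(i) {
    m <- layer@polygons[[i]]
    ring <- rbind(m, m[1, ])  # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(use_class = layer@useClass[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r)
                                                     as.numeric(ring[r, ])))))
  })
  .geojsonWrite(feats, path)
}

#' @rdname writeLandUseGeoJSON
#' @export
readLandUseGeoJSON <- function(path) {
  feats <- .geojsonRead(path)
  polys <- list(); cls <- character()
  for (f in feats) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("land-use features must be Polygons")
    ring <- .coordsToMatrix(f$geometry$coordinates[[1]])
    .checkProjected(ring, "land-use")
    n <- nrow(ring)
    if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    polys[[length(polys) + 1L]] <- ring
    cls <- c(cls, f$properties$use_class)
  }
  landUseLayer(polys, cls)
}

#' Household GeoJSON I/O
#'
#' One Point feature per household.
#'
#' @param layer a \linkS4class{HouseholdLayer}.
#' @param path file path.
#' @return \code{readHouseholdsGeoJSON} returns a
#'   \linkS4class{HouseholdLayer}.
#' @export
writeHouseholdsGeoJSON <- function(layer, path) {
  feats <- lapply(seq_len(nrow(layer@coords)), function(i)
    list(type = "Feature", properties = structure(list(), names = character()),
         geometry = list(type = "Point",
                         coordinates = as.numeric(layer@coords[i, ]))))
  .geojsonWrite(feats, path)
}

#' @rdname writeHouseholdsGeoJSON
#' @export
readHouseholdsGeoJSON <- function(path) {
  feats <- .geojsonRead(path)
  if (!length(feats)) return(householdLayer())
  xy <- .coordsToMatrix(lapply(feats, function(f) f$geometry$coordinates))
  .checkProjected(xy, "household")
  householdLayer(xy)
}

## ---- ESRI ASCII raster -----------------------------------------------------

#' ESRI ASCII grid I/O for the vegetation raster
#'
#' Plain-text ESRI ASCII format (\code{ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value} header, rows north to south).
#'
#' @param raster a \linkS4class{RasterGrid}.
#' @param path file path.
#' @return \code{readAsciiGrid} returns a \linkS4class{RasterGrid}.
#' @export
writeAsciiGrid <- function(raster, path) {
  v <- raster@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.6f", raster@xll),
               sprintf("yllcorner %.6f", raster@yll),
               sprintf("cellsize %.6f", raster@cellSize),
               "NODATA_value -9999"), con)
  v[is.na(v)] <- -9999
  for (i in rev(seq_len(nrow(v))))  # file rows run north to south
    writeLines(paste(format(v[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (suppressWarnings(is.na(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("incomplete ESRI ASCII header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = lines[(i + 1L):length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first rows
  rasterGrid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, m)
}

## ---- tabular / JSON artifacts ---------------------------------------------

#' Write the per-site noise metrics CSV
#'
#' One row per site: \code{site_id,l_day,l_evening,l_night,l_aeq24h,l_den,
#' fraction_missing,n_outliers_removed,valid}. Excluded sites appear with
#' \code{valid = FALSE} and NA metrics.
#'
#' @param metrics data.frame in the output schema (e.g. rbind of
#'   \code{as.data.frame(NoiseMetrics)} rows).
#' @param path CSV file path.
#' @export
writeNoiseMetricsCsv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Feature matrix CSV I/O
#'
#' The CSV holds one row per site (\code{site_id,x,y,area} then one column
#' per variable); a sidecar JSON carries the column metadata (category,
#' variable type, buffer, expected sign, unit).
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param path CSV path; the sidecar defaults to the same path with
#'   \code{_meta.json} appended in place of \code{.csv}.
#' @param metaPath sidecar JSON path.
#' @return \code{readFeatureMatrixCsv} returns a
#'   \linkS4class{FeatureMatrix}.
#' @export
writeFeatureMatrixCsv <- function(fm, path,
                                  metaPath = sub("\\.csv$", "_meta.json",
                                                 path)) {
  X <- t(SummarizedExperiment::assay(fm, "features"))
  sites <- as.data.frame(SummarizedExperiment::colData(fm))
  out <- cbind(sites[, c("site_id", "x", "y", "area")],
               as.data.frame(X, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  meta <- as.data.frame(SummarizedExperiment::rowData(fm))
  jsonlite::write_json(meta, metaPath, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeFeatureMatrixCsv
#' @export
readFeatureMatrixCsv <- function(path,
                                 metaPath = sub("\\.csv$", "_meta.json",
                                                path)) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(metaPath)
  vars <- meta$name
  featureMatrix(t(as.matrix(tab[, vars, drop = FALSE])), meta,
                tab[, c("site_id", "x", "y", "area")])
}

#' LUR model JSON I/O
#'
#' Serializes the fitted model: selected variables with their metadata,
#' coefficients, intercept, standard errors, p-values, R-squared values,
#' the selection thresholds and the full selection trace.
#'
#' @param model a \linkS4class{LURModel}.
#' @param path JSON file path.
#' @return \code{readModelJson} returns a \linkS4class{LURModel}.
#' @export
writeModelJson <- function(model, path) {
  fit <- model@fit
  obj <- list(
    variables = as.data.frame(model@variableData),
    intercept = unname(fit@coefficients["(Intercept)"]),
    coefficients = as.list(fit@coefficients[fit@variables]),
    standard_errors = as.list(fit@se),
    p_values = as.list(fit@pValues),
    r2 = fit@r2, adjusted_r2 = fit@adjR2, n_sites = fit@n,
    fitted = unname(fit@fitted), residuals = unname(fit@residuals),
    config = model@config, trace = model@trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::fromJSON(path)
  vars <- obj$variables$name
  coefs <- c(`(Intercept)` = obj$intercept, unlist(obj$coefficients))
  fit <- new("RegressionFit", variables = as.character(vars),
             coefficients = coefs, se = unlist(obj$standard_errors),
             pValues = unlist(obj$p_values), r2 = obj$r2,
             adjR2 = obj$adjusted_r2, fitted = obj$fitted,
             residuals = obj$residuals, n = as.integer(obj$n_sites))
  new("LURModel", fit = fit, trace = as.data.frame(obj$trace),
      config = as.list(obj$config),
      variableData = S4Vectors::DataFrame(obj$variables,
                                          row.names = vars))
}
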