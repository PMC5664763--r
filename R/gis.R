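#' @include AllClasses.R geometry.R
NULL

# Composite road variable types: each is the sum of the class-specific
# clipped lengths (identical to re-clipping the union for non-overlapping
# geometries, and cheaper).
.ROAD_TYPES <- list(
  road_large = "large",
  road_medium = "medium",
  road_small = "small",
  road_very_small = "very_small",
  road_large_medium = c("large", "medium"),
  road_large_medium_small = c("large", "medium", "small"),
  road_all = c("large", "medium", "small", "very_small"),
  road_medium_small = c("medium", "small"),
  road_medium_small_very_small = c("medium", "small", "very_small"),
  road_small_very_small = c("small", "very_small"))

.ROAD_RADII <- c(25, 50, 100, 200, 500)
.DENSITY_RADII <- c(25, 50, 100, 200, 500, 750, 1000)
.LANDUSE_RADII <- c(25, 50, 100, 200, 500, 750, 1000)
.NDVI_RADII <- c(30, 100, 150, 200, 500, 750)

.siteXY <- function(site) {
  if (is.numeric(site) && length(site) == 2L) return(as.numeric(site))
  if (is.list(site) || is.data.frame(site)) return(c(site$x[1], site$y[1]))
  stop("site must be an (x, y) pair or a row with x and y fields")
}

# Flatten a RoadNetwork into per-class segment coordinate vectors.
.segmentsByClass <- function(network) {
  out <- list()
  for (cl in .ROAD_CLASSES) {
    idx <- which(network@roadClass == cl)
    x1 <- y1 <- x2 <- y2 <- numeric()
    for (i in idx) {
      m <- network@coords[[i]]
      n <- nrow(m)
      x1 <- c(x1, m[-n, 1]); y1 <- c(y1, m[-n, 2])
      x2 <- c(x2, m[-1, 1]); y2 <- c(y2, m[-1, 2])
    }
    out[[cl]] <- list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  }
  out
}

#' Road length within a circular buffer
#'
#' Total length of the clipped intersection of all road segments of the
#' given classes with the closed disc of radius \code{radiusM} centred at
#' the site. Clipping is exact (analytic segment-circle intersection).
#'
#' @param network a \linkS4class{RoadNetwork}.
#' @param classes subset of road classes to include.
#' @param site an (x, y) coordinate pair (metres, projected) or a row with
#'   \code{x} and \code{y} fields.
#' @param radiusM buffer radius in metres.
#' @return Clipped length in metres.
#' @examples
#' rn <- roadNetwork(list(cbind(c(-1000, 1000), c(0, 0))), "large")
#' lineLengthInBuffer(rn, "large", c(0, 0), 200)   # diametral chord: 400
#' @export
lineLengthInBuffer <- function(network, classes, site, radiusM) {
  stopifnot(radiusM > 0)
  classes <- unique(as.character(classes))
  if (length(classes) == 0L) stop("empty road class subset")
  if (!all(classes %in% .ROAD_CLASSES))
    stop("unknown road class: ", paste(setdiff(classes, .ROAD_CLASSES),
                                       collapse = ", "))
  xy <- .siteXY(site)
  total <- 0
  for (i in seq_along(network@coords)) {
    if (!(network@roadClass[i] %in% classes)) next
    total <- total + .polylineClipLength(network@coords[[i]], xy[1], xy[2],
                                         radiusM)
  }
  total
}

#' Inverse distance to the nearest feature
#'
#' Returns \code{1 / max(d, 1)} where \code{d} is the Euclidean distance in
#' metres from the site to the nearest feature. The 1-metre floor bounds
#' the variable when a site touches a feature, so that a single coincident
#' point cannot dominate the regression screen.
#'
#' @param site an (x, y) coordinate pair or a row with \code{x}, \code{y}.
#' @param features a \linkS4class{PointFeatureSet} or, for the nearest-road
#'   variable, a \linkS4class{RoadNetwork}.
#' @return Inverse distance in 1/m.
#' @export
inverseDistance <- function(site, features) {
  xy <- .siteXY(site)
  if (is(features, "PointFeatureSet")) {
    if (nrow(features@coords) == 0L)
      stop(sprintf("empty feature set '%s'", features@category))
    d <- sqrt(min((features@coords[, 1] - xy[1])^2 +
                  (features@coords[, 2] - xy[2])^2))
  } else if (is(features, "RoadNetwork")) {
    if (length(features@coords) == 0L) stop("empty road network")
    d <- min(vapply(features@coords, .pointPolylineDistance, numeric(1),
                    cx = xy[1], cy = xy[2]))
  } else stop("features must be a PointFeatureSet or RoadNetwork")
  1 / max(d, 1)
}

#' Household density within a circular buffer
#'
#' Number of household points within the closed disc, divided by the buffer
#' surface in square metres.
#'
#' @param households a \linkS4class{HouseholdLayer}.
#' @param site an (x, y) coordinate pair or a row with \code{x}, \code{y}.
#' @param radiusM buffer radius in metres.
#' @return Density in households per square metre (multiply by 1e4 for
#'   homes per hectare).
#' @export
householdDensity <- function(households, site, radiusM) {
  stopifnot(radiusM > 0)
  xy <- .siteXY(site)
  cnt <- if (nrow(households@coords) == 0L) 0L else
    sum((households@coords[, 1] - xy[1])^2 +
        (households@coords[, 2] - xy[2])^2 <= radiusM^2)
  cnt / (pi * radiusM^2)
}

#' Land-use area within a circular buffer
#'
#' Area of the intersection of all polygons of the given class with the
#' closed disc. The intersection area is computed exactly by a per-edge
#' decomposition into chord triangles and circular sectors.
#'
#' @param layer a \linkS4class{LandUseLayer}.
#' @param useClass one land-use class.
#' @param site an (x, y) coordinate pair or a row with \code{x}, \code{y}.
#' @param radiusM buffer radius in metres.
#' @return Intersection area in square metres.
#' @export
landUseAreaInBuffer <- function(layer, useClass, site, radiusM) {
  stopifnot(radiusM > 0, length(useClass) == 1L)
  if (!useClass %in% .LANDUSE_CLASSES)
    stop("unknown land-use class: ", useClass)
  xy <- .siteXY(site)
  total <- 0
  for (i in seq_along(layer@polygons)) {
    if (layer@useClass[i] != useClass) next
    total <- total + .polygonDiscArea(layer@polygons[[i]], xy[1], xy[2],
                                      radiusM)
  }
  total
}

#' Mean raster value within a circular buffer
#'
#' Mean of the cells whose centres fall within the closed disc, ignoring
#' missing cells (cell-centre inclusion rule).
#'
#' @param raster a \linkS4class{RasterGrid}.
#' @param site an (x, y) coordinate pair or a row with \code{x}, \code{y}.
#' @param radiusM buffer radius in metres.
#' @return Mean cell value.
#' @export
rasterMeanInBuffer <- function(raster, site, radiusM) {
  stopifnot(radiusM > 0)
  xy <- .siteXY(site)
  cs <- raster@cellSize
  nr <- nrow(raster@values); nc <- ncol(raster@values)
  jlo <- max(1L, ceiling((xy[1] - radiusM - raster@xll) / cs + 0.5 - 1e-9))
  jhi <- min(nc, floor((xy[1] + radiusM - raster@xll) / cs + 0.5 + 1e-9))
  ilo <- max(1L, ceiling((xy[2] - radiusM - raster@yll) / cs + 0.5 - 1e-9))
  ihi <- min(nr, floor((xy[2] + radiusM - raster@yll) / cs + 0.5 + 1e-9))
  if (jlo > jhi || ilo > ihi)
    stop("buffer does not overlap the raster extent")
  jj <- jlo:jhi; ii <- ilo:ihi
  cx <- raster@xll + (jj - 0.5) * cs
  cy <- raster@yll + (ii - 0.5) * cs
  d2 <- outer(cy - xy[2], cx - xy[1], function(a, b) a^2 + b^2)
  v <- raster@values[ii, jj, drop = FALSE][d2 <= radiusM^2 + 1e-9]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("no non-missing raster cells within the buffer")
  mean(v)
}

#' The candidate predictor grid
#'
#' Builds the full grid of candidate LUR predictors: clipped lengths of ten
#' road class combinations at 25/50/100/200/500 m; inverse distances to the
#' nearest road, airport, active railway, any railway, church, police
#' station and hospital; household density and five land-use class areas at
#' 25/50/100/200/500/750/1000 m; and mean NDVI at 30/100/150/200/500/750 m
#' (105 variables). Expected signs encode the prior direction of effect on
#' noise: positive for roads, inverse distances, household density and
#' commercial/industrial/buildings land use; negative for residential and
#' nature land use and for NDVI.
#'
#' @return data.frame with columns \code{name}, \code{category},
#'   \code{var_type}, \code{buffer_m}, \code{expected_sign}, \code{unit}.
#' @examples
#' nrow(candidateVariables())  # 105
#' @export
candidateVariables <- function() {
  rows <- list()
  for (tp in names(.ROAD_TYPES))
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(tp, "_", .ROAD_RADII), category = "roads",
      var_type = tp, buffer_m = .ROAD_RADII, expected_sign = 1, unit = "m")
  inv <- data.frame(
    name = c("invdist_road", "invdist_airport", "invdist_railway_active",
             "invdist_railway_any", "invdist_church", "invdist_police",
             "invdist_hospital"),
    category = c("roads", "air", "rail", "rail", "community", "community",
                 "community"),
    var_type = c("invdist_road", "invdist_airport", "invdist_railway_active",
                 "invdist_railway_any", "invdist_church", "invdist_police",
                 "invdist_hospital"),
    buffer_m = NA_real_, expected_sign = 1, unit = "1/m")
  rows[[length(rows) + 1L]] <- inv
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste0("hh_density_", .DENSITY_RADII), category = "buildings",
    var_type = "hh_density", buffer_m = .DENSITY_RADII, expected_sign = 1,
    unit = "1/m2")
  luSign <- c(residential = -1, commercial = 1, industrial = 1,
              buildings = 1, nature = -1)
  for (cl in .LANDUSE_CLASSES)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("landuse_", cl, "_", .LANDUSE_RADII),
      category = "land_use", var_type = paste0("landuse_", cl),
      buffer_m = .LANDUSE_RADII, expected_sign = unname(luSign[cl]),
      unit = "m2")
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste0("ndvi_", .NDVI_RADII), category = "vegetation",
    var_type = "ndvi", buffer_m = .NDVI_RADII, expected_sign = -1,
    unit = "index")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the sites-by-predictors feature matrix
#'
#' Computes every candidate predictor for every site from the supplied
#' layers. Variables whose source layer is absent — or, for inverse
#' distances, empty — are dropped with a warning; all other variables are
#' computed densely (an empty household layer yields zero densities, an
#' empty road network zero lengths).
#'
#' @param sites data.frame with columns \code{site_id}, \code{x}, \code{y}
#'   and optionally \code{area}.
#' @param layers named list with elements \code{roads}
#'   (\linkS4class{RoadNetwork}), \code{points} (named list of
#'   \linkS4class{PointFeatureSet}, names being the categories),
#'   \code{landuse} (\linkS4class{LandUseLayer}), \code{households}
#'   (\linkS4class{HouseholdLayer}) and \code{ndvi}
#'   (\linkS4class{RasterGrid}). Any element may be NULL.
#' @param variables candidate grid as returned by
#'   \code{\link{candidateVariables}} (rows may be dropped to restrict the
#'   grid).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
buildFeatureMatrix <- function(sites, layers, variables = candidateVariables()) {
  stopifnot(all(c("site_id", "x", "y") %in% names(sites)))
  if (anyDuplicated(sites$site_id))
    stop("site_id values must be unique")
  if (!"area" %in% names(sites)) sites$area <- NA_character_
  nS <- nrow(sites)

  drop <- character()
  roads <- layers$roads
  if (is.null(roads) || length(roads@coords) == 0L) {
    drop <- c(drop, variables$name[variables$var_type %in% names(.ROAD_TYPES)],
              "invdist_road")
    roads <- NULL
  }
  pointCats <- sub("^invdist_", "",
                   grep("^invdist_(?!road$)", variables$name, perl = TRUE,
                        value = TRUE))
  for (cat in pointCats) {
    pf <- layers$points[[cat]]
    if (is.null(pf) || nrow(pf@coords) == 0L)
      drop <- c(drop, paste0("invdist_", cat))
  }
  if (is.null(layers$households))
    drop <- c(drop, variables$name[variables$var_type == "hh_density"])
  if (is.null(layers$landuse))
    drop <- c(drop, variables$name[startsWith(variables$var_type, "landuse_")])
  if (is.null(layers$ndvi))
    drop <- c(drop, variables$name[variables$var_type == "ndvi"])
  drop <- intersect(unique(drop), variables$name)
  if (length(drop)) {
    warning("dropping variables with empty or missing source layers: ",
            paste(drop, collapse = ", "))
    variables <- variables[!variables$name %in% drop, , drop = FALSE]
  }
  if (nrow(variables) == 0L) stop("no computable candidate variables remain")

  segs <- if (!is.null(roads)) .segmentsByClass(roads)
  lu <- layers$landuse
  if (!is.null(lu)) {
    # per-polygon bounding boxes and areas for disc fast paths
    luBB <- t(vapply(lu@polygons, function(p)
      c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), numeric(4)))
    luArea <- vapply(lu@polygons, function(p) abs(.ringArea(p)), numeric(1))
  }

  vals <- matrix(NA_real_, nrow(variables), nS,
                 dimnames = list(variables$name, sites$site_id))
  roadVars <- variables[variables$var_type %in% names(.ROAD_TYPES), ]
  hhVars <- variables[variables$var_type == "hh_density", ]
  ndviVars <- variables[variables$var_type == "ndvi", ]
  luClasses <- unique(sub("^landuse_", "",
                          variables$var_type[startsWith(variables$var_type,
                                                        "landuse_")]))
  for (i in seq_len(nS)) {
    cx <- sites$x[i]; cy <- sites$y[i]
    if (!is.null(roads)) {
      classLen <- matrix(0, 4, length(.ROAD_RADII),
                         dimnames = list(.ROAD_CLASSES, NULL))
      for (cl in .ROAD_CLASSES) {
        s <- segs[[cl]]
        if (!length(s$x1)) next
        for (k in seq_along(.ROAD_RADII))
          classLen[cl, k] <- sum(.segClipLength(s$x1, s$y1, s$x2, s$y2,
                                                cx, cy, .ROAD_RADII[k]))
      }
      for (r in seq_len(nrow(roadVars))) {
        k <- match(roadVars$buffer_m[r], .ROAD_RADII)
        vals[roadVars$name[r], i] <-
          sum(classLen[.ROAD_TYPES[[roadVars$var_type[r]]], k])
      }
      if ("invdist_road" %in% variables$name)
        vals["invdist_road", i] <- inverseDistance(c(cx, cy), roads)
    }
    for (cat in pointCats) {
      nm <- paste0("invdist_", cat)
      if (nm %in% variables$name)
        vals[nm, i] <- inverseDistance(c(cx, cy), layers$points[[cat]])
    }
    if (nrow(hhVars)) {
      hc <- layers$households@coords
      d2 <- if (nrow(hc)) (hc[, 1] - cx)^2 + (hc[, 2] - cy)^2 else numeric()
      for (r in seq_len(nrow(hhVars))) {
        rad <- hhVars$buffer_m[r]
        vals[hhVars$name[r], i] <- sum(d2 <= rad^2) / (pi * rad^2)
      }
    }
    if (length(luClasses)) {
      dxb <- pmax(0, luBB[, 1] - cx, cx - luBB[, 2])
      dyb <- pmax(0, luBB[, 3] - cy, cy - luBB[, 4])
      near2 <- dxb^2 + dyb^2
      fxb <- pmax(abs(luBB[, 1] - cx), abs(luBB[, 2] - cx))
      fyb <- pmax(abs(luBB[, 3] - cy), abs(luBB[, 4] - cy))
      far2 <- fxb^2 + fyb^2
      for (rad in .LANDUSE_RADII) {
        a <- numeric(length(lu@polygons))
        insideAll <- far2 <= rad^2
        a[insideAll] <- luArea[insideAll]
        edge <- which(!insideAll & near2 <= rad^2)
        for (p in edge)
          a[p] <- .polygonDiscArea(lu@polygons[[p]], cx, cy, rad)
        byClass <- rowsum(a, lu@useClass)
        for (cl in luClasses) {
          nm <- paste0("landuse_", cl, "_", rad)
          if (nm %in% variables$name)
            vals[nm, i] <- if (cl %in% rownames(byClass))
              byClass[cl, 1] else 0
        }
      }
    }
    for (r in seq_len(nrow(ndviVars)))
      vals[ndviVars$name[r], i] <-
        rasterMeanInBuffer(layers$ndvi, c(cx, cy), ndviVars$buffer_m[r])
  }
  featureMatrix(vals, variables,
                sites[, c("site_id", "x", "y", "area")])
}

#' @rdname accessors
#' @export
featureValues <- function(x) SummarizedExperiment::assay(x, "features")

#' @rdname accessors
#' @export
variableData <- function(x) {
  if (is(x, "LURModel")) return(x@variableData)
  SummarizedExperiment::rowData(x)
}

#' @rdname accessors
#' @export
siteData <- function(x) SummarizedExperiment::colData(x)
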