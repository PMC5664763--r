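#' @include AllClasses.R gis.R acoustics.R
NULL

# Seeded sub-streams: one child seed per generator component, so changing
# one component's configuration does not perturb the others.
.childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2^31 - 2, n)
}

#' Configuration of a synthetic settlement layout
#'
#' Describes the square study region the layout generator emulates: an
#' informal-settlement-like mosaic of land-use tiles, road chords of four
#' classes, households clustered around the monitoring sites, community
#' point features, and a smooth vegetation-index field. The extent must be
#' at least twice the largest buffer radius (1000 m) so buffers fit.
#'
#' @param extentM side of the square region in metres.
#' @param nSites number of monitoring sites.
#' @param roadsPerClass named counts of random road chords per class.
#' @param nHouseholds total household points.
#' @param householdClusterSd Gaussian scatter (m) of households around
#'   their site cluster centre.
#' @param householdBackgroundFrac fraction of households placed uniformly
#'   rather than clustered.
#' @param landTileM edge of the square land-use tiles.
#' @param landUseProbs named sampling probabilities of the five classes.
#' @param pointCounts named point-feature counts (\code{railway_any} is the
#'   union of \code{railway_active} and \code{railway_inactive}).
#' @param ndviCellM NDVI raster cell size in metres.
#' @param ndviSmoothCells half-width (cells) of the smoothing window.
#' @param ndviMean,ndviSd target mean and SD of the NDVI field.
#' @param seed integer seed; the layout is reproducible given the seed.
#' @return list of class \code{"LayoutConfig"}.
#' @export
layoutConfig <- function(extentM = 3000, nSites = 50,
                         roadsPerClass = c(large = 4, medium = 6, small = 14,
                                           very_small = 24),
                         nHouseholds = 4000, householdClusterSd = 150,
                         householdBackgroundFrac = 0.3, landTileM = 250,
                         landUseProbs = c(residential = 0.45,
                                          commercial = 0.15,
                                          industrial = 0.10,
                                          buildings = 0.15, nature = 0.15),
                         pointCounts = c(airport = 1, railway_active = 1,
                                         railway_inactive = 1, church = 5,
                                         police = 2, hospital = 2),
                         ndviCellM = 30, ndviSmoothCells = 7,
                         ndviMean = 0.25, ndviSd = 0.15, seed = 1) {
  stopifnot(extentM >= 2000, nSites >= 0, all(roadsPerClass >= 0),
            nHouseholds >= 0, all(pointCounts >= 0), ndviCellM > 0)
  structure(list(extentM = extentM, nSites = nSites,
                 roadsPerClass = roadsPerClass, nHouseholds = nHouseholds,
                 householdClusterSd = householdClusterSd,
                 householdBackgroundFrac = householdBackgroundFrac,
                 landTileM = landTileM, landUseProbs = landUseProbs,
                 pointCounts = pointCounts, ndviCellM = ndviCellM,
                 ndviSmoothCells = ndviSmoothCells, ndviMean = ndviMean,
                 ndviSd = ndviSd, seed = seed),
            class = "LayoutConfig")
}

# Running mean with half-width h, edge windows shrink (no NA).
.blur1d <- function(v, h) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(0L, i - h - 1L)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Generate a synthetic settlement layout
#'
#' Produces monitoring sites and every predictor layer the feature module
#' consumes. Roads are random chords across the region; households follow
#' an inhomogeneous point process clustered around the sites (with a
#' uniform background component); land use is a tile mosaic covering the
#' region; the vegetation index is a smoothed Gaussian random field clipped
#' to [-1, 1]. Sites carry one of four quadrant area labels, mimicking a
#' multi-area study. Fully reproducible given the config seed; each
#' component draws from its own seeded stream.
#'
#' @param config a \code{\link{layoutConfig}}.
#' @return list with \code{sites} (data.frame: site_id, x, y, area) and
#'   \code{layers} (list: roads, points, landuse, households, ndvi).
#' @export
generateLayout <- function(config = layoutConfig()) {
  stopifnot(inherits(config, "LayoutConfig"))
  E <- config$extentM
  seeds <- .childSeeds(config$seed, 6)

  set.seed(seeds[1])  # sites
  n <- config$nSites
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(max(n, 0))),
    x = stats::runif(n, 0.05 * E, 0.95 * E),
    y = stats::runif(n, 0.05 * E, 0.95 * E))
  sites$area <- paste0("area", 1L + (sites$x > E / 2) + 2L * (sites$y > E / 2))

  set.seed(seeds[2])  # roads
  coords <- list(); cls <- character()
  for (cl in .ROAD_CLASSES) {
    k <- config$roadsPerClass[[cl]]
    if (is.null(k) || k == 0) next
    for (i in seq_len(k)) {
      seg <- NULL
      while (is.null(seg))
        seg <- .clipLineToBox(stats::runif(1, 0, E), stats::runif(1, 0, E),
                              stats::runif(1, 0, pi), E)
      coords[[length(coords) + 1L]] <- seg
      cls <- c(cls, cl)
    }
  }
  roads <- roadNetwork(coords, cls)

  set.seed(seeds[3])  # households
  nh <- config$nHouseholds
  hh <- matrix(numeric(), ncol = 2)
  if (nh > 0) {
    nbg <- round(config$householdBackgroundFrac * nh)
    ncl <- nh - nbg
    bg <- cbind(stats::runif(nbg, 0, E), stats::runif(nbg, 0, E))
    if (ncl > 0 && n > 0) {
      w <- stats::rexp(n) + 0.1       # uneven cluster weights across sites
      idx <- sample.int(n, ncl, replace = TRUE, prob = w / sum(w))
      pts <- cbind(sites$x[idx] + stats::rnorm(ncl, 0, config$householdClusterSd),
                   sites$y[idx] + stats::rnorm(ncl, 0, config$householdClusterSd))
    } else pts <- cbind(stats::runif(ncl, 0, E), stats::runif(ncl, 0, E))
    hh <- rbind(bg, pts)
    hh[, 1] <- pmin(pmax(hh[, 1], 0), E)
    hh[, 2] <- pmin(pmax(hh[, 2], 0), E)
  }
  households <- householdLayer(hh)

  set.seed(seeds[4])  # land-use mosaic
  tile <- config$landTileM
  nt <- ceiling(E / tile)
  classes <- sample(names(config$landUseProbs), nt * nt, replace = TRUE,
                    prob = config$landUseProbs)
  polys <- vector("list", nt * nt)
  k <- 0L
  for (iy in seq_len(nt)) for (ix in seq_len(nt)) {
    k <- k + 1L
    x0 <- (ix - 1) * tile; y0 <- (iy - 1) * tile
    x1 <- min(ix * tile, E); y1 <- min(iy * tile, E)
    polys[[k]] <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  }
  landuse <- landUseLayer(polys, classes)

  set.seed(seeds[5])  # point features
  pc <- config$pointCounts
  rnd <- function(k) cbind(stats::runif(k, 0, E), stats::runif(k, 0, E))
  act <- rnd(pc[["railway_active"]])
  inact <- rnd(pc[["railway_inactive"]])
  points <- list(
    airport = pointFeatureSet("airport", rnd(pc[["airport"]])),
    railway_active = pointFeatureSet("railway_active", act),
    railway_any = pointFeatureSet("railway_any", rbind(act, inact)),
    church = pointFeatureSet("church", rnd(pc[["church"]])),
    police = pointFeatureSet("police", rnd(pc[["police"]])),
    hospital = pointFeatureSet("hospital", rnd(pc[["hospital"]])))

  set.seed(seeds[6])  # NDVI field
  ng <- ceiling(E / config$ndviCellM)
  field <- matrix(stats::rnorm(ng * ng), ng, ng)
  h <- config$ndviSmoothCells
  field <- apply(field, 2, .blur1d, h = h)
  field <- t(apply(field, 1, .blur1d, h = h))
  field <- (field - mean(field)) / stats::sd(field)
  field <- config$ndviMean + config$ndviSd * field
  field <- pmin(pmax(field, -1), 1)
  ndvi <- rasterGrid(0, 0, config$ndviCellM, field)

  list(sites = sites,
       layers = list(roads = roads, points = points, landuse = landuse,
                     households = households, ndvi = ndvi))
}

# Default ground-truth coefficients for the five generating predictors.
# Signs follow the fitted model's direction of effect (road traffic,
# household density, commercial and industrial land use all increase
# noise); magnitudes are scaled so that, under the default layout, each
# predictor contributes roughly 2 dB of between-site SD, giving a total
# response SD near the ~4.7 dB observed for Lden in the field.
.defaultTruthBeta <- function() {
  c(hh_density_50 = 6600,            # dB per (household/m2); 0.66 dB per home/ha
    road_medium_25 = 0.14,           # dB per m of medium road in 25 m
    road_large_200 = 0.01,           # dB per m of large road in 200 m
    landuse_commercial_50 = 8e-4,    # dB per m2 commercial in 50 m
    landuse_industrial_50 = 1e-3)    # dB per m2 industrial in 50 m
}

#' Ground-truth linear model for the synthetic response
#'
#' The synthetic Lden surface is linear in a small set of generating
#' predictors plus Gaussian noise. Defaults use the field-observed
#' direction of effects (household density, medium- and large-road length,
#' commercial and industrial land use, all positive) with magnitudes scaled
#' to the synthetic layout and an intercept near the observed mean Lden.
#'
#' @param beta0 intercept in dB(A).
#' @param beta named coefficient vector; names must be feature-matrix
#'   columns.
#' @param sigma residual SD in dB.
#' @return list of class \code{"TruthModel"}.
#' @export
truthModel <- function(beta0 = 61.3, beta = .defaultTruthBeta(), sigma = 1) {
  stopifnot(sigma >= 0, is.numeric(beta0))
  if (length(beta) && is.null(names(beta)))
    stop("beta must be a named vector of feature coefficients")
  structure(list(beta0 = beta0, beta = beta, sigma = sigma),
            class = "TruthModel")
}

#' Generate a synthetic per-site response
#'
#' Computes \code{y = beta0 + sum(beta_k * x_k) + eps} with
#' \code{eps ~ N(0, sigma^2)} i.i.d. over sites, seeded.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param truth a \code{\link{truthModel}}.
#' @param seed integer seed for the residual draw.
#' @return Named numeric vector of per-site levels in dB(A).
#' @export
generateResponse <- function(features, truth, seed = 1) {
  stopifnot(inherits(truth, "TruthModel"))
  X <- SummarizedExperiment::assay(features, "features")
  unknown <- setdiff(names(truth$beta), rownames(X))
  if (length(unknown))
    stop("truth coefficients name unknown features: ",
         paste(unknown, collapse = ", "))
  mu <- rep(truth$beta0, ncol(X))
  if (length(truth$beta))
    mu <- mu + drop(crossprod(X[names(truth$beta), , drop = FALSE],
                              truth$beta))
  set.seed(seed)
  y <- mu + stats::rnorm(ncol(X), 0, truth$sigma)
  names(y) <- colnames(X)
  y
}

#' Configuration of a synthetic 1-second level series
#'
#' Describes one logger deployment: target period levels, the within-period
#' dB scatter, a contiguous missing gap, and isolated 1-second spikes.
#'
#' @param siteId site identifier the series is labelled with.
#' @param targets named day/evening/night target period levels in dB(A).
#' @param withinSd within-period SD of the 1-s dB levels.
#' @param missingFraction fraction of the window removed as one contiguous
#'   gap (emulating battery failure), in [0, 1).
#' @param spikeRatePerHour expected number of injected spikes per hour.
#' @param spikeMagnitudeDb magnitude added to a spiked second, dB.
#' @param seed integer seed.
#' @return list of class \code{"SeriesConfig"}.
#' @export
seriesConfig <- function(siteId = "S001",
                         targets = c(day = 60, evening = 55, night = 50),
                         withinSd = 3, missingFraction = 0,
                         spikeRatePerHour = 0, spikeMagnitudeDb = 25,
                         seed = 1) {
  stopifnot(all(c("day", "evening", "night") %in% names(targets)),
            withinSd >= 0, missingFraction >= 0, missingFraction < 1,
            spikeRatePerHour >= 0, spikeMagnitudeDb > 0)
  structure(list(siteId = siteId, targets = targets, withinSd = withinSd,
                 missingFraction = missingFraction,
                 spikeRatePerHour = spikeRatePerHour,
                 spikeMagnitudeDb = spikeMagnitudeDb, seed = seed),
            class = "SeriesConfig")
}

#' Generate a raw 1-second level series
#'
#' Draws per-second dB levels around the period targets such that the
#' energetic period mean of the clean series matches each target (the
#' Gaussian dB scatter inflates energetic means by
#' \code{sd^2 * ln(10) / 20}, which is subtracted from the draw mean), then
#' removes one contiguous gap totalling \code{missingFraction} of the
#' window and injects isolated single-second spikes at the configured rate.
#' Spike timestamps and the gap position are recorded in the series
#' metadata for sensitivity bookkeeping.
#'
#' @param config a \code{\link{seriesConfig}}.
#' @param window an \linkS4class{AnalysisWindow}.
#' @return A \linkS4class{SoundLevelSeries}.
#' @export
generateSeries <- function(config = seriesConfig(), window = analysisWindow()) {
  stopifnot(inherits(config, "SeriesConfig"))
  set.seed(config$seed)
  n <- as.integer(window@expectedSeconds)
  tnum <- as.numeric(window@start) + seq_len(n) - 1
  hour <- (tnum %% 86400) %/% 3600
  periodIdx <- ifelse(hour >= 6 & hour < 18, 1L,
                      ifelse(hour >= 18 & hour < 22, 2L, 3L))
  s <- config$withinSd
  mu <- config$targets[c("day", "evening", "night")] - s^2 * log(10) / 20
  level <- stats::rnorm(n, mu[periodIdx], s)

  keep <- rep(TRUE, n)
  gap <- NULL
  if (config$missingFraction > 0) {
    gapLen <- round(config$missingFraction * n)
    gapStart <- sample.int(n - gapLen + 1L, 1L)
    keep[gapStart:(gapStart + gapLen - 1L)] <- FALSE
    gap <- c(start = gapStart, length = gapLen)
  }
  spikeIdx <- integer()
  if (config$spikeRatePerHour > 0) {
    nSpikes <- stats::rpois(1, config$spikeRatePerHour * n / 3600)
    avail <- which(keep)
    nSpikes <- min(nSpikes, length(avail))
    spikeIdx <- sort(sample(avail, nSpikes))
    level[spikeIdx] <- level[spikeIdx] + config$spikeMagnitudeDb
  }
  level <- pmin(pmax(level, 0), 140)
  tm <- as.POSIXct(tnum[keep], origin = "1970-01-01", tz = "UTC")
  new("SoundLevelSeries", siteId = config$siteId, time = tm,
      level = level[keep],
      metadata = list(
        spike_times = as.POSIXct(tnum[spikeIdx], origin = "1970-01-01",
                                 tz = "UTC"),
        gap = gap, config = config))
}
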