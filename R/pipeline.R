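#' @include AllClasses.R lur.R synthetic.R io.R
NULL

#' Predict noise levels from a fitted LUR model
#'
#' Linear prediction: intercept plus the coefficient-weighted selected
#' predictors. No extrapolation guard is applied: predictions at sites
#' whose predictor values lie outside the training range are returned
#' as-is.
#'
#' @param object a \linkS4class{LURModel}.
#' @param features a \linkS4class{FeatureMatrix} containing every model
#'   variable.
#' @return Named numeric vector of predicted levels in dB(A).
#' @export
setMethod("predict", "LURModel", function(object, features) {
  X <- .featuresBySite(features)
  vars <- object@fit@variables
  missing <- setdiff(vars, colnames(X))
  if (length(missing))
    stop("feature matrix lacks model variables: ",
         paste(missing, collapse = ", "))
  beta <- object@fit@coefficients
  drop(beta["(Intercept)"] +
       X[, vars, drop = FALSE] %*% beta[vars])
})

#' @rdname predict-LURModel-method
#' @param model a \linkS4class{LURModel}.
#' @export
predictNoise <- function(model, features) predict(model, features)

# Binned proportions over half-open dB classes of the given width; the
# default [45, 80) span is extended as needed to cover the data.
.binProportions <- function(x, width = 2.5, lo = 45, hi = 80) {
  while (min(x) < lo) lo <- lo - width
  while (max(x) >= hi) hi <- hi + width
  breaks <- seq(lo, hi, by = width)
  p <- table(cut(x, breaks, right = FALSE)) / length(x)
  stats::setNames(as.numeric(p), levels(cut(x, breaks, right = FALSE)))
}

#' Evaluate predictions against measurements
#'
#' Computes the squared Pearson correlation between predicted and measured
#' levels, overall and within each study area (areas with fewer than three
#' sites, or with degenerate variance, report NA), residual diagnostics
#' including a descriptive Shapiro-Wilk statistic on the standardized
#' residuals, and binned level distributions for both series.
#'
#' @param predicted,measured aligned per-site levels in dB(A).
#' @param areas per-site area labels (optional).
#' @param binWidth histogram class width in dB (default 2.5).
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluateModel <- function(predicted, measured, areas = NULL, binWidth = 2.5) {
  stopifnot(length(predicted) == length(measured))
  r2of <- function(p, m) {
    if (length(p) < 3L || stats::sd(p) == 0 || stats::sd(m) == 0)
      return(NA_real_)
    stats::cor(p, m)^2
  }
  r2 <- r2of(predicted, measured)
  if (is.na(r2)) {
    warning("overall R2 undefined (degenerate predictions or measurements); ",
            "reporting 0")
    r2 <- 0
  }
  byArea <- numeric()
  if (!is.null(areas)) {
    stopifnot(length(areas) == length(measured))
    for (a in sort(unique(areas))) {
      sel <- areas == a
      byArea[a] <- r2of(predicted[sel], measured[sel])
    }
  }
  res <- measured - predicted
  z <- if (stats::sd(res) > 0) (res - mean(res)) / stats::sd(res) else res
  normality <- if (length(z) >= 3 && stats::sd(res) > 0) {
    sw <- stats::shapiro.test(z)
    list(statistic = unname(sw$statistic), p_value = sw$p.value)
  } else list(statistic = NA_real_, p_value = NA_real_)
  new("EvaluationReport", r2Overall = r2, r2ByArea = byArea,
      residuals = res, predicted = as.numeric(predicted),
      measured = as.numeric(measured), normality = normality,
      histMeasured = .binProportions(measured, binWidth),
      histPredicted = .binProportions(predicted, binWidth),
      binWidth = binWidth)
}

#' Pipeline configuration
#'
#' Bundles the analysis window, cleaning thresholds, selection thresholds
#' and input/output paths for an end-to-end run.
#'
#' @param inputDir directory holding \code{sites.csv}, a \code{series/}
#'   directory of per-site CSVs, \code{roads.geojson},
#'   \code{points.geojson}, \code{landuse.geojson},
#'   \code{households.geojson} and \code{ndvi.asc} (any layer may be
#'   absent; its variables are dropped).
#' @param outDir output directory for the artifacts.
#' @param window an \linkS4class{AnalysisWindow}.
#' @param maxMissing completeness threshold (fraction, default 0.10).
#' @param outlierSd outlier threshold in SDs (default 3).
#' @param selection thresholds from \code{\link{lurConfig}}.
#' @param variables candidate grid (default the full
#'   \code{\link{candidateVariables}} grid).
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(inputDir, outDir = tempfile("noiselur_out"),
                           window = analysisWindow(), maxMissing = 0.10,
                           outlierSd = 3, selection = lurConfig(),
                           variables = candidateVariables()) {
  stopifnot(maxMissing > 0, outlierSd > 0)
  structure(list(inputDir = inputDir, outDir = outDir, window = window,
                 maxMissing = maxMissing, outlierSd = outlierSd,
                 selection = selection, variables = variables),
            class = "PipelineConfig")
}

#' Read a pipeline configuration file
#'
#' JSON (or YAML, if the yaml package is installed) file with any of the
#' fields \code{input_dir}, \code{out_dir}, \code{window_start},
#' \code{max_missing}, \code{outlier_sd}, \code{corr_threshold},
#' \code{p_remove}, \code{p_keep}.
#'
#' @param path configuration file path.
#' @return A \code{\link{pipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  pipelineConfig(
    inputDir = cfg$input_dir,
    outDir = if (!is.null(cfg$out_dir)) cfg$out_dir else
      tempfile("noiselur_out"),
    window = if (!is.null(cfg$window_start))
      analysisWindow(as.POSIXct(cfg$window_start, tz = "UTC")) else
      analysisWindow(),
    maxMissing = if (!is.null(cfg$max_missing)) cfg$max_missing else 0.10,
    outlierSd = if (!is.null(cfg$outlier_sd)) cfg$outlier_sd else 3,
    selection = lurConfig(
      corrThreshold = if (!is.null(cfg$corr_threshold)) cfg$corr_threshold
        else 0.7,
      pRemove = if (!is.null(cfg$p_remove)) cfg$p_remove else 0.2,
      pKeep = if (!is.null(cfg$p_keep)) cfg$p_keep else 0.2))
}

.log <- function(fmt, ...) message(sprintf(paste0("[noiseLUR] ", fmt), ...))

#' Run the full measurement-to-model pipeline
#'
#' Reads the site table, per-site raw series and GIS layers from the input
#' directory; computes cleaned noise metrics (excluding sites that fail
#' the completeness rule); builds the feature matrix for the retained
#' sites; fits the LUR model for Lden by supervised selection; predicts at
#' the training sites and evaluates. Writes
#' \code{noise_metrics.csv}, \code{feature_matrix.csv} (+ metadata JSON),
#' \code{lur_model.json} and \code{evaluation.json} to the output
#' directory. Deterministic: identical inputs give identical artifacts.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisible list with the metrics table, feature matrix, model
#'   and evaluation report.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dirIn <- config$inputDir
  dirOut <- config$outDir
  if (!dir.exists(dirOut)) dir.create(dirOut, recursive = TRUE)

  sites <- readSites(file.path(dirIn, "sites.csv"))
  .log("read %d sites", nrow(sites))

  metricRows <- list()
  metricsBySite <- list()
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    f <- file.path(dirIn, "series", paste0(sid, ".csv"))
    if (!file.exists(f))
      stop(sprintf("stage metrics: missing series file for site '%s'", sid))
    series <- readLevelSeries(f, siteId = sid)
    m <- tryCatch(computeMetrics(series, config$window), error = function(e) {
      if (inherits(e, "noiseLUR_site_excluded")) e else stop(e)
    })
    if (inherits(m, "noiseLUR_site_excluded")) {
      r <- m$report
      .log("site %s excluded: %.1f%% missing", sid, 100 * r@fractionMissing)
      metricRows[[sid]] <- data.frame(
        site_id = sid, l_day = NA_real_, l_evening = NA_real_,
        l_night = NA_real_, l_aeq24h = NA_real_, l_den = NA_real_,
        fraction_missing = r@fractionMissing,
        n_outliers_removed = NA_real_, valid = FALSE)
    } else {
      metricRows[[sid]] <- as.data.frame(m)
      metricsBySite[[sid]] <- m
    }
  }
  metrics <- do.call(rbind, metricRows)
  rownames(metrics) <- NULL
  writeNoiseMetricsCsv(metrics, file.path(dirOut, "noise_metrics.csv"))
  .log("metrics: %d sites retained, %d excluded", length(metricsBySite),
       nrow(sites) - length(metricsBySite))
  if (length(metricsBySite) < 3L)
    stop("stage fit: fewer than 3 valid sites remain")

  kept <- sites[sites$site_id %in% names(metricsBySite), , drop = FALSE]
  layers <- list(
    roads = if (file.exists(file.path(dirIn, "roads.geojson")))
      readRoadsGeoJSON(file.path(dirIn, "roads.geojson")),
    points = if (file.exists(file.path(dirIn, "points.geojson")))
      readPointsGeoJSON(file.path(dirIn, "points.geojson")),
    landuse = if (file.exists(file.path(dirIn, "landuse.geojson")))
      readLandUseGeoJSON(file.path(dirIn, "landuse.geojson")),
    households = if (file.exists(file.path(dirIn, "households.geojson")))
      readHouseholdsGeoJSON(file.path(dirIn, "households.geojson")),
    ndvi = if (file.exists(file.path(dirIn, "ndvi.asc")))
      readAsciiGrid(file.path(dirIn, "ndvi.asc")))
  fm <- buildFeatureMatrix(kept, layers, config$variables)
  .log("features: %d candidate variables at %d sites", nrow(fm), ncol(fm))
  writeFeatureMatrixCsv(fm, file.path(dirOut, "feature_matrix.csv"))

  lden <- vapply(metricsBySite[kept$site_id], function(m) m@lDen, numeric(1))
  model <- buildLUR(fm, lden, config$selection)
  .log("model: %d variables selected, adj. R2 = %.3f",
       length(selectedVariables(model)), adjustedR2(model))
  writeModelJson(model, file.path(dirOut, "lur_model.json"))

  pred <- predict(model, fm)
  ev <- evaluateModel(pred, lden, areas = kept$area)
  jsonlite::write_json(
    list(r2_overall = ev@r2Overall, r2_by_area = as.list(ev@r2ByArea),
         normality = ev@normality,
         histogram_measured = as.list(ev@histMeasured),
         histogram_predicted = as.list(ev@histPredicted),
         residuals = unname(ev@residuals), predicted = unname(ev@predicted),
         measured = unname(ev@measured)),
    file.path(dirOut, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  .log("evaluation: overall R2 = %.3f", ev@r2Overall)

  invisible(list(metrics = metrics, features = fm, model = model,
                 evaluation = ev))
}

#' Simulate a complete synthetic study on disk
#'
#' Generates a layout, its feature matrix and a ground-truth Lden surface,
#' derives per-site day/evening/night targets from each site's Lden using
#' a fixed diurnal profile (normalized so the series-implied Lden equals
#' the surface value), writes raw 1-second series and all GIS layers in
#' the formats the pipeline reads, plus \code{truth.json} with the
#' generating coefficients.
#'
#' @param outDir output directory.
#' @param layout a \code{\link{layoutConfig}}.
#' @param truth a \code{\link{truthModel}}.
#' @param window an \linkS4class{AnalysisWindow}.
#' @param seriesSd within-period SD of the 1-s levels, dB.
#' @param missingFraction per-site missing fractions (recycled).
#' @param spikeRatePerHour per-site spike rates (recycled).
#' @param seed integer seed.
#' @return Invisible list with the layout, feature matrix and true Lden.
#' @export
simulateStudy <- function(outDir, layout = layoutConfig(),
                          truth = truthModel(), window = analysisWindow(),
                          seriesSd = 3, missingFraction = 0,
                          spikeRatePerHour = 0, seed = 1) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  dir.create(file.path(outDir, "series"), showWarnings = FALSE)
  lay <- generateLayout(layout)
  fm <- buildFeatureMatrix(lay$sites, lay$layers)
  lden <- generateResponse(fm, truth, seed = seed)

  # diurnal profile shaped like the observed period means, shifted so the
  # implied Lden reproduces each site's surface value exactly
  off <- c(day = -3.0, evening = -2.3, night = -10.1)
  off <- off - (ldenFromComponents(off["day"], off["evening"], off["night"]))
  n <- nrow(lay$sites)
  mf <- rep_len(missingFraction, n)
  sr <- rep_len(spikeRatePerHour, n)
  seeds <- .childSeeds(seed + 1L, n)
  for (i in seq_len(n)) {
    sid <- lay$sites$site_id[i]
    cfg <- seriesConfig(siteId = sid,
                        targets = c(day = lden[[sid]] + off[["day"]],
                                    evening = lden[[sid]] + off[["evening"]],
                                    night = lden[[sid]] + off[["night"]]),
                        withinSd = seriesSd, missingFraction = mf[i],
                        spikeRatePerHour = sr[i], seed = seeds[i])
    writeLevelSeries(generateSeries(cfg, window),
                     file.path(outDir, "series", paste0(sid, ".csv")))
  }
  writeSites(lay$sites, file.path(outDir, "sites.csv"))
  writeRoadsGeoJSON(lay$layers$roads, file.path(outDir, "roads.geojson"))
  writePointsGeoJSON(lay$layers$points, file.path(outDir, "points.geojson"))
  writeLandUseGeoJSON(lay$layers$landuse, file.path(outDir, "landuse.geojson"))
  writeHouseholdsGeoJSON(lay$layers$households,
                         file.path(outDir, "households.geojson"))
  writeAsciiGrid(lay$layers$ndvi, file.path(outDir, "ndvi.asc"))
  jsonlite::write_json(
    list(beta0 = truth$beta0, beta = as.list(truth$beta),
         sigma = truth$sigma, seed = seed,
         window_start = format(window@start, .tsFormat, tz = "UTC"),
         true_lden = as.list(lden)),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(layout = lay, features = fm, lden = lden))
}
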