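#' @include AllClasses.R
NULL

#' Accessors for noiseLUR objects
#'
#' @param x a noiseLUR object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname accessors
#' @export
setMethod("siteId", "SoundLevelSeries", function(x) x@siteId)

#' @rdname accessors
#' @export
setMethod("siteId", "NoiseMetrics", function(x) x@siteId)

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setMethod("sampleTimes", "SoundLevelSeries", function(x) x@time)

#' @rdname accessors
#' @export
setGeneric("dbLevels", function(x) standardGeneric("dbLevels"))

#' @rdname accessors
#' @export
setMethod("dbLevels", "SoundLevelSeries", function(x) x@level)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setMethod("nSamples", "SoundLevelSeries", function(x) length(x@level))

#' @rdname accessors
#' @export
setGeneric("cleaningReport", function(x) standardGeneric("cleaningReport"))

#' @rdname accessors
#' @export
setMethod("cleaningReport", "NoiseMetrics", function(x) x@report)

#' @rdname accessors
#' @export
setGeneric("selectedVariables", function(x) standardGeneric("selectedVariables"))

#' @rdname accessors
#' @export
setMethod("selectedVariables", "LURModel", function(x) x@fit@variables)

#' @rdname accessors
#' @export
setMethod("selectedVariables", "RegressionFit", function(x) x@variables)

#' @rdname accessors
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))

#' @rdname accessors
#' @export
setMethod("selectionTrace", "LURModel", function(x) x@trace)

#' @rdname accessors
#' @export
setGeneric("modelFit", function(x) standardGeneric("modelFit"))

#' @rdname accessors
#' @export
setMethod("modelFit", "LURModel", function(x) x@fit)

#' @rdname accessors
#' @export
setGeneric("adjustedR2", function(x) standardGeneric("adjustedR2"))

#' @rdname accessors
#' @export
setMethod("adjustedR2", "RegressionFit", function(x) x@adjR2)

#' @rdname accessors
#' @export
setMethod("adjustedR2", "LURModel", function(x) x@fit@adjR2)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setMethod("rSquared", "RegressionFit", function(x) x@r2)

#' @rdname accessors
#' @export
setMethod("rSquared", "LURModel", function(x) x@fit@r2)

#' @rdname accessors
#' @export
setMethod("coef", "RegressionFit", function(object) object@coefficients)

#' @rdname accessors
#' @export
setMethod("coef", "LURModel", function(object) object@fit@coefficients)

#' @rdname accessors
#' @export
setMethod("residuals", "RegressionFit", function(object) object@residuals)

#' @rdname accessors
#' @export
setMethod("fitted", "RegressionFit", function(object) object@fitted)

#' Convert noise metrics to a one-row data.frame
#'
#' @param x a \linkS4class{NoiseMetrics} object.
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return A one-row data.frame matching the output CSV schema.
#' @export
as.data.frame.NoiseMetrics <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  r <- x@report
  data.frame(site_id = x@siteId, l_day = x@lDay, l_evening = x@lEvening,
             l_night = x@lNight, l_aeq24h = x@lAeq24h, l_den = x@lDen,
             fraction_missing = r@fractionMissing,
             n_outliers_removed = r@nOutliersRemoved, valid = r@valid,
             stringsAsFactors = FALSE)
}

setMethod("show", "SoundLevelSeries", function(object) {
  n <- length(object@level)
  cat(sprintf("SoundLevelSeries '%s': %d samples", object@siteId, n))
  if (n) cat(sprintf(" [%s .. %s], %.1f-%.1f dB(A)",
                     format(object@time[1]), format(object@time[n]),
                     min(object@level), max(object@level)))
  cat("\n")
})

setMethod("show", "AnalysisWindow", function(object) {
  cat(sprintf("AnalysisWindow: %s -> %s (%d expected seconds)\n",
              format(object@start), format(object@end),
              as.integer(object@expectedSeconds)))
})

setMethod("show", "CleaningReport", function(object) {
  cat(sprintf(paste0("CleaningReport: %s/%s samples (%.2f%% missing), ",
                     "%s outliers removed, valid = %s\n"),
              format(object@nPresent), format(object@nExpected),
              100 * object@fractionMissing, format(object@nOutliersRemoved),
              object@valid))
})

setMethod("show", "NoiseMetrics", function(object) {
  cat(sprintf("NoiseMetrics '%s' [dB(A)]\n", object@siteId))
  v <- c(Lday = object@lDay, Levening = object@lEvening,
         Lnight = object@lNight, LAeq24h = object@lAeq24h, Lden = object@lDen)
  print(round(v, 2))
})

setMethod("show", "RoadNetwork", function(object) {
  cat(sprintf("RoadNetwork: %d polylines (%s)\n", length(object@coords),
              paste(sprintf("%s: %d", names(table(object@roadClass)),
                            table(object@roadClass)), collapse = ", ")))
})

setMethod("show", "PointFeatureSet", function(object) {
  cat(sprintf("PointFeatureSet '%s': %d points\n", object@category,
              nrow(object@coords)))
})

setMethod("show", "LandUseLayer", function(object) {
  cat(sprintf("LandUseLayer: %d polygons (%s)\n", length(object@polygons),
              paste(sprintf("%s: %d", names(table(object@useClass)),
                            table(object@useClass)), collapse = ", ")))
})

setMethod("show", "HouseholdLayer", function(object) {
  cat(sprintf("HouseholdLayer: %d households\n", nrow(object@coords)))
})

setMethod("show", "RasterGrid", function(object) {
  cat(sprintf("RasterGrid: %d x %d cells of %.0f m, origin (%.0f, %.0f)\n",
              nrow(object@values), ncol(object@values), object@cellSize,
              object@xll, object@yll))
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit: %d variables, n = %d, R2 = %.3f, adj. R2 = %.3f\n",
              length(object@variables), object@n, object@r2, object@adjR2))
  if (length(object@variables)) {
    tab <- data.frame(coef = object@coefficients, se = object@se,
                      p = object@pValues)
    print(round(tab, 4))
  }
})

setMethod("show", "LURModel", function(object) {
  cat("LURModel (supervised stepwise selection)\n")
  show(object@fit)
  cat(sprintf("Trace: %d events; thresholds: |r| < %.2f, p <= %.2f\n",
              nrow(object@trace), object@config$corrThreshold,
              object@config$pRemove))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: overall R2 = %.3f (n = %d)\n",
              object@r2Overall, length(object@measured)))
  if (length(object@r2ByArea)) {
    cat("Per-area R2:\n")
    print(round(object@r2ByArea, 3))
  }
})
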