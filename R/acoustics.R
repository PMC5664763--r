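#' @include AllClasses.R
NULL

#' Period definitions for the noise metrics
#'
#' The 24-hour cycle is partitioned into day (06:00-18:00), evening
#' (18:00-22:00) and night (22:00-06:00, wrapping midnight); \code{full}
#' denotes the whole 06:00-06:00 cycle. The Lden penalties are +5 dB on
#' evening and +10 dB on night energy. Daily activity in the study setting
#' begins early, hence the 06:00 day start.
#'
#' @return data.frame with columns \code{name}, \code{start_hour},
#'   \code{end_hour}, \code{duration_hours}, \code{penalty_db}.
#' @examples
#' noisePeriods()
#' @export
noisePeriods <- function() {
  data.frame(
    name = c("day", "evening", "night", "full"),
    start_hour = c(6L, 18L, 22L, 6L),
    end_hour = c(18L, 22L, 6L, 6L),
    duration_hours = c(12L, 4L, 8L, 24L),
    penalty_db = c(0L, 5L, 10L, 0L),
    stringsAsFactors = FALSE)
}

#' Energetic (equal-energy) mean of dB values
#'
#' Averages sound levels on the linear energy scale:
#' \code{10 * log10(mean(10^(level / 10)))}. This is the aggregation
#' underlying every LAeq-type metric and is always at least the arithmetic
#' mean of the dB values.
#'
#' @param levels numeric vector of dB values.
#' @return The equivalent level in dB.
#' @examples
#' energeticMean(c(50, 60))  # 57.40, dominated by the louder level
#' @export
energeticMean <- function(levels) {
  if (length(levels) == 0L) stop("no samples in period")
  if (any(!is.finite(levels))) stop("levels must be finite")
  10 * log10(mean(10^(levels / 10)))
}

#' Day-evening-night level from its period components
#'
#' Combines the three period levels with duration weights (12 h day, 4 h
#' evening, 8 h night) after adding the +5 dB evening and +10 dB night
#' penalties on the energy scale:
#' \deqn{L_{den} = 10 \log_{10}\!\big( (12 \cdot 10^{L_{day}/10} +
#'   4 \cdot 10^{(L_{evening}+5)/10} + 8 \cdot 10^{(L_{night}+10)/10}) / 24 \big)}
#'
#' @param lDay,lEvening,lNight period levels in dB(A).
#' @return Lden in dB(A).
#' @examples
#' ldenFromComponents(60, 60, 60)  # 66.40
#' @export
ldenFromComponents <- function(lDay, lEvening, lNight) {
  stopifnot(is.finite(lDay), is.finite(lEvening), is.finite(lNight))
  10 * log10((12 * 10^(lDay / 10) +
              4 * 10^((lEvening + 5) / 10) +
              8 * 10^((lNight + 10) / 10)) / 24)
}

#' Restrict a series to the analysis window
#'
#' Keeps exactly the samples with \code{start <= t < end}, preserving
#' order. Measurements run for about a week; the analysis is restricted to
#' the same five successive days (Wednesday 06:00 to Monday 06:00) at every
#' site.
#'
#' @param series a \linkS4class{SoundLevelSeries}.
#' @param window an \linkS4class{AnalysisWindow}.
#' @return The restricted \linkS4class{SoundLevelSeries}.
#' @export
restrictToWindow <- function(series, window) {
  t <- as.numeric(series@time)
  keep <- t >= as.numeric(window@start) & t < as.numeric(window@end)
  if (!any(keep)) stop("no data in analysis window")
  if (all(keep)) return(series)
  new("SoundLevelSeries", siteId = series@siteId,
      time = series@time[keep], level = series@level[keep],
      metadata = series@metadata)
}

#' Assess completeness against the analysis window
#'
#' Computes the missing fraction against the 432,000 expected one-second
#' samples and applies the exclusion rule: sites with data missing for more
#' than 10% of the time (e.g. battery failure) are invalid. Exactly 10%
#' missing is retained, the rule being strictly greater-than.
#'
#' @param series a window-restricted \linkS4class{SoundLevelSeries}.
#' @param window an \linkS4class{AnalysisWindow}.
#' @param maxMissing maximum tolerated missing fraction (default 0.10).
#' @return A \linkS4class{CleaningReport} with the missingness fields set.
#' @export
assessCompleteness <- function(series, window, maxMissing = 0.10) {
  nExp <- window@expectedSeconds
  nPres <- length(series@level)
  frac <- 1 - nPres / nExp
  .cleaningReport(nExpected = nExp, nPresent = nPres, fractionMissing = frac,
                  valid = frac <= maxMissing + 1e-12)
}

#' Remove 3-SD outliers from a series
#'
#' Outliers are one-second measurements deviating from the five-day
#' arithmetic mean of the dB values by more than three standard deviations
#' (also on the dB scale). Removal is a single pass: the mean and SD are
#' computed once on the input and not re-estimated after removal. A
#' constant series (SD = 0) yields zero removals.
#'
#' @param series a window-restricted, completeness-valid
#'   \linkS4class{SoundLevelSeries}.
#' @param nSd removal threshold in standard deviations (default 3).
#' @return list with elements \code{series} (cleaned) and \code{report}
#'   (a \linkS4class{CleaningReport} with \code{meanDb}, \code{sdDb} and
#'   \code{nOutliersRemoved} set).
#' @export
removeOutliers <- function(series, nSd = 3) {
  lv <- series@level
  if (length(lv) == 0L) stop("series is empty")
  m <- mean(lv)
  s <- if (length(lv) > 1L) stats::sd(lv) else 0
  keep <- if (s > 0) abs(lv - m) <= nSd * s else rep(TRUE, length(lv))
  nRemoved <- sum(!keep)
  out <- if (nRemoved > 0)
    new("SoundLevelSeries", siteId = series@siteId, time = series@time[keep],
        level = lv[keep], metadata = series@metadata)
  else series
  list(series = out,
       report = .cleaningReport(nPresent = length(lv), meanDb = m, sdDb = s,
                                nOutliersRemoved = nRemoved))
}

#' Equivalent level over one period of the diurnal cycle
#'
#' Pools all samples across all days of the window whose local clock time
#' falls in the period (night wraps midnight; \code{full} takes every
#' sample) and returns their energetic mean.
#'
#' @param series a cleaned \linkS4class{SoundLevelSeries}.
#' @param period one of \code{"day"}, \code{"evening"}, \code{"night"},
#'   \code{"full"}.
#' @return The period level in dB(A).
#' @export
periodLevel <- function(series, period = c("day", "evening", "night", "full")) {
  period <- match.arg(period)
  lv <- series@level
  if (period != "full") {
    hour <- (as.numeric(series@time) %% 86400) %/% 3600
    sel <- switch(period,
      day = hour >= 6 & hour < 18,
      evening = hour >= 18 & hour < 22,
      night = hour >= 22 | hour < 6)
    lv <- lv[sel]
  }
  if (length(lv) == 0L) stop(sprintf("no samples in period '%s'", period))
  energeticMean(lv)
}

#' Compute the five noise metrics for one site
#'
#' Runs the full cleaning and aggregation chain on a raw series: restrict
#' to the five-day window, reject the site if more than 10% of the expected
#' seconds are missing, remove 3-SD outliers in a single pass, compute
#' Lday, Levening, Lnight and LAeq24h by energetic pooling, and derive Lden
#' from the three period components with the evening/night penalties.
#'
#' @param series a raw \linkS4class{SoundLevelSeries}.
#' @param window an \linkS4class{AnalysisWindow}.
#' @return A \linkS4class{NoiseMetrics} object; its report records the
#'   missingness and outlier bookkeeping.
#' @section Errors:
#' If the completeness rule fails, a condition of class
#' \code{"noiseLUR_site_excluded"} is signalled with the
#' \linkS4class{CleaningReport} attached as its \code{report} field.
#' @examples
#' w <- analysisWindow()
#' s <- soundLevelSeries("S1", windowStart(w) + 0:(432000 - 1),
#'                       rep(60, 432000))
#' computeMetrics(s, w)  # all periods 60.00, Lden 66.40
#' @export
computeMetrics <- function(series, window) {
  restricted <- restrictToWindow(series, window)
  comp <- assessCompleteness(restricted, window)
  if (!isTRUE(comp@valid)) {
    cond <- structure(
      class = c("noiseLUR_site_excluded", "error", "condition"),
      list(message = sprintf(
             "site '%s' excluded: %.1f%% of the window missing (> 10%%)",
             restricted@siteId, 100 * comp@fractionMissing),
           call = sys.call(), report = comp))
    stop(cond)
  }
  cleaned <- removeOutliers(restricted)
  report <- .cleaningReport(
    nExpected = comp@nExpected, nPresent = comp@nPresent,
    fractionMissing = comp@fractionMissing,
    meanDb = cleaned$report@meanDb, sdDb = cleaned$report@sdDb,
    nOutliersRemoved = cleaned$report@nOutliersRemoved, valid = TRUE)
  s <- cleaned$series
  lDay <- periodLevel(s, "day")
  lEvening <- periodLevel(s, "evening")
  lNight <- periodLevel(s, "night")
  lAeq24h <- periodLevel(s, "full")
  new("NoiseMetrics", siteId = s@siteId, lDay = lDay, lEvening = lEvening,
      lNight = lNight, lAeq24h = lAeq24h,
      lDen = ldenFromComponents(lDay, lEvening, lNight), report = report)
}
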