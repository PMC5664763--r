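# Cleaning and aggregation of 1-second level series.

test_that("energetic mean matches direct evaluation and its invariants", {
  expect_equal(energeticMean(rep(53.7, 1000)), 53.7)
  expect_equal(energeticMean(c(50, 60)), 10 * log10((1e5 + 1e6) / 2),
               tolerance = 1e-12)
  expect_equal(energeticMean(c(60, 60, 60, 70)),
               10 * log10((3 * 1e6 + 1e7) / 4), tolerance = 1e-12)
  # Jensen: energetic mean dominates the arithmetic dB mean
  set.seed(1)
  for (i in 1:20) {
    x <- runif(50, 30, 90)
    expect_gte(energeticMean(x), mean(x))
  }
  expect_error(energeticMean(numeric()), "no samples")
})

test_that("Lden combines period components with duration-weighted penalties", {
  expect_equal(ldenFromComponents(60, 60, 60),
               10 * log10((12 * 1e6 + 4 * 10^6.5 + 8 * 1e7) / 24),
               tolerance = 1e-12)
  # evening + 5 and night + 10 equal the day level: all terms coincide
  expect_equal(ldenFromComponents(60, 55, 50), 60, tolerance = 1e-12)
  # very quiet evening and night leave only the 12/24 day term
  expect_equal(ldenFromComponents(70, -200, -200), 70 + 10 * log10(12 / 24),
               tolerance = 1e-9)
})

test_that("window restriction keeps exactly the half-open five-day span", {
  w <- testWindow
  # a 7-day deployment starting Monday 12:00 before the window
  t0 <- windowStart(w) - 42 * 3600
  s <- soundLevelSeries("S1", t0 + seq(0, 7 * 86400 - 1, by = 600),
                        rep(60, 1008))
  r <- restrictToWindow(s, w)
  expect_true(all(sampleTimes(r) >= windowStart(w)))
  expect_true(all(sampleTimes(r) < windowEnd(w)))
  expect_equal(nSamples(r), sum(t0 + seq(0, 7 * 86400 - 1, by = 600) >=
                                  windowStart(w) &
                                t0 + seq(0, 7 * 86400 - 1, by = 600) <
                                  windowEnd(w)))
  # series exactly spanning the window passes through unchanged
  full <- constantSeries()
  expect_identical(restrictToWindow(full, w), full)
  # series ending early retains only the overlap
  early <- soundLevelSeries("S2", windowStart(w) + 0:9999, rep(55, 10000))
  expect_equal(nSamples(restrictToWindow(early, w)), 10000)
  # no overlap at all signals
  off <- soundLevelSeries("S3", windowEnd(w) + 1:10, rep(60, 10))
  expect_error(restrictToWindow(off, w), "no data in analysis window")
})

test_that("the 10% missingness rule excludes strictly above the boundary", {
  w <- testWindow
  full <- assessCompleteness(constantSeries(n = 432000), w)
  expect_equal(full@fractionMissing, 0)
  expect_true(full@valid)
  atBoundary <- assessCompleteness(constantSeries(n = 388800), w)
  expect_equal(atBoundary@fractionMissing, 0.10, tolerance = 1e-9)
  expect_true(atBoundary@valid)   # exactly 10% is retained
  over <- assessCompleteness(constantSeries(n = 388799), w)
  expect_false(over@valid)        # 0.1000023 > 0.10
})

test_that("outlier removal is a single 3-SD pass on the dB scale", {
  w <- testWindow
  # constant series: SD = 0, nothing removed
  res <- removeOutliers(constantSeries(n = 1000))
  expect_equal(res$report@nOutliersRemoved, 0)
  expect_equal(nSamples(res$series), 1000)
  # one large spike among many identical-ish samples is removed
  lv <- c(rep(60, 100000), 120)
  s <- soundLevelSeries("S1", windowStart(w) + seq_along(lv) - 1, lv)
  res <- removeOutliers(s)
  expect_equal(res$report@nOutliersRemoved, 1)
  expect_false(120 %in% dbLevels(res$series))
  expect_equal(res$report@meanDb, mean(lv))
  expect_equal(res$report@sdDb, sd(lv))
  # removal never re-evaluates: count of survivors is fixed by one pass
  expect_equal(nSamples(res$series), 100000)
})

test_that("Gaussian series lose about the 3-SD two-sided tail mass", {
  w <- testWindow
  set.seed(99)
  lv <- pmin(pmax(rnorm(432000, 60, 4), 0), 140)
  s <- soundLevelSeries("G", windowStart(w) + seq_along(lv) - 1, lv)
  res <- removeOutliers(s)
  frac <- res$report@nOutliersRemoved / 432000
  expected <- 2 * pnorm(-3)  # 0.0027
  expect_lt(abs(frac - expected), 5e-4)
})

test_that("period levels pool clock-time classes across days", {
  w <- testWindow
  n <- 432000
  tm <- windowStart(w) + seq_len(n) - 1
  hour <- (as.numeric(tm) %% 86400) %/% 3600
  lv <- ifelse(hour >= 6 & hour < 18, 60, 50)
  s <- soundLevelSeries("S1", tm, lv)
  expect_equal(periodLevel(s, "day"), 60)
  expect_equal(periodLevel(s, "evening"), 50)
  expect_equal(periodLevel(s, "night"), 50)
  expect_equal(periodLevel(s, "full"), 10 * log10((12 * 1e6 + 12 * 1e5) / 24),
               tolerance = 1e-9)
  con <- constantSeries(61.3, n = 86400)
  for (p in c("day", "evening", "night", "full"))
    expect_equal(periodLevel(con, p), 61.3)
})

test_that("computeMetrics composes cleaning and aggregation", {
  w <- testWindow
  m <- computeMetrics(constantSeries(60), w)
  expect_equal(m@lDay, 60)
  expect_equal(m@lEvening, 60)
  expect_equal(m@lNight, 60)
  expect_equal(m@lAeq24h, 60)
  expect_equal(m@lDen, ldenFromComponents(60, 60, 60))
  expect_true(cleaningReport(m)@valid)
  # a site with an 11% gap is excluded with the report attached
  n11 <- round(432000 * 0.89)
  short <- constantSeries(60, n = n11)
  err <- tryCatch(computeMetrics(short, w), condition = identity)
  expect_s3_class(err, "noiseLUR_site_excluded")
  expect_equal(err$report@fractionMissing, 0.11, tolerance = 1e-5)
})

test_that("metric invariants hold across random diurnal series", {
  w <- testWindow
  set.seed(5)
  for (i in 1:5) {
    cfg <- seriesConfig(targets = c(day = runif(1, 50, 70),
                                    evening = runif(1, 45, 65),
                                    night = runif(1, 40, 60)),
                        withinSd = runif(1, 1, 4), seed = i)
    m <- computeMetrics(generateSeries(cfg, w), w)
    expect_gte(m@lDen, m@lAeq24h - 1e-9)
    expect_lte(m@lDen, m@lAeq24h + 10 + 1e-9)
    per <- c(m@lDay, m@lEvening, m@lNight)
    expect_gte(m@lAeq24h, min(per) - 1e-9)
    expect_lte(m@lAeq24h, max(per) + 1e-9)
  }
})

test_that("series CSV round trip preserves the metrics", {
  w <- testWindow
  cfg <- seriesConfig(targets = c(day = 62, evening = 58, night = 51),
                      seed = 3)
  s <- generateSeries(cfg, w)
  f <- tempfile(fileext = ".csv")
  writeLevelSeries(s, f)
  s2 <- readLevelSeries(f, siteId = siteId(s))
  expect_equal(nSamples(s2), nSamples(s))
  m1 <- computeMetrics(s, w)
  m2 <- computeMetrics(s2, w)
  expect_equal(m2@lDen, m1@lDen, tolerance = 1e-9)
  unlink(f)
})
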