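# Buffer geometry and feature extraction.

test_that("road clipping reproduces closed-form chord lengths", {
  rn <- roadNetwork(list(cbind(c(-2000, 2000), c(0, 0))), "large")
  # diametral chord
  expect_equal(lineLengthInBuffer(rn, "large", c(0, 0), 200), 400)
  # road entirely outside the disc
  expect_equal(lineLengthInBuffer(rn, "large", c(0, 300), 200), 0)
  # off-centre chord 2 * sqrt(r^2 - d^2)
  expect_equal(lineLengthInBuffer(rn, "large", c(0, 100), 200),
               2 * sqrt(200^2 - 100^2), tolerance = 1e-9)
  # polyline split across vertices clips identically
  rn2 <- roadNetwork(list(cbind(c(-2000, -50, 10, 2000), c(0, 0, 0, 0))),
                     "medium")
  expect_equal(lineLengthInBuffer(rn2, "medium", c(0, 0), 200), 400,
               tolerance = 1e-9)
  expect_error(lineLengthInBuffer(rn, character(), c(0, 0), 100),
               "empty road class")
})

test_that("clipped lengths agree with dense point-sampling quadrature", {
  set.seed(11)
  for (i in 1:10) {
    p1 <- runif(2, -500, 500); p2 <- runif(2, -500, 500)
    r <- runif(1, 50, 400)
    rn <- roadNetwork(list(rbind(p1, p2)), "small")
    got <- lineLengthInBuffer(rn, "small", c(0, 0), r)
    tt <- seq(0, 1, length.out = 200001)
    pts <- cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]))
    inside <- pts[, 1]^2 + pts[, 2]^2 <= r^2
    approx <- mean(inside) * sqrt(sum((p2 - p1)^2))
    expect_equal(got, approx, tolerance = 5e-3)
  }
})

test_that("class-partition additivity and radius monotonicity hold", {
  lay <- smallLayout(seed = 3, nSites = 10)
  rn <- lay$layers$roads
  radii <- c(25, 50, 100, 200, 500)
  for (i in 1:5) {
    site <- c(lay$sites$x[i], lay$sites$y[i])
    all5 <- vapply(radii, function(r)
      lineLengthInBuffer(rn, c("large", "medium", "small", "very_small"),
                         site, r), numeric(1))
    parts <- sapply(c("large", "medium", "small", "very_small"),
                    function(cl) vapply(radii, function(r)
                      lineLengthInBuffer(rn, cl, site, r), numeric(1)))
    expect_equal(rowSums(parts), all5, tolerance = 1e-9)
    expect_true(all(diff(all5) >= -1e-9))  # monotone in radius
  }
})

test_that("inverse distance floors at one metre and takes the nearest", {
  ch <- pointFeatureSet("church", rbind(c(100, 0), c(500, 0)))
  expect_equal(inverseDistance(c(0, 0), ch), 0.01)
  expect_equal(inverseDistance(c(100, 0), ch), 1)   # coincident, floored
  two <- pointFeatureSet("police", rbind(c(50, 0), c(0, 500)))
  expect_equal(inverseDistance(c(0, 0), two), 1 / 50)
  expect_error(inverseDistance(c(0, 0), pointFeatureSet("airport")),
               "empty feature set")
  # nearest road uses point-to-segment distance
  rn <- roadNetwork(list(cbind(c(-1000, 1000), c(80, 80))), "large")
  expect_equal(inverseDistance(c(0, 0), rn), 1 / 80)
})

test_that("household density is count over buffer surface", {
  set.seed(2)
  hh <- householdLayer(cbind(runif(10, -30, 30), runif(10, -30, 30)))
  d <- householdDensity(hh, c(0, 0), 50)
  expect_equal(d, 10 / (pi * 2500), tolerance = 1e-12)
  expect_equal(d * 1e4, 12.73, tolerance = 0.01)  # homes per hectare
  expect_equal(householdDensity(householdLayer(), c(0, 0), 100), 0)
})

test_that("polygon-disc intersection matches geometric oracles", {
  big <- cbind(c(-1e4, 1e4, 1e4, -1e4), c(-1e4, -1e4, 1e4, 1e4))
  half <- cbind(c(0, 1e4, 1e4, 0), c(-1e4, -1e4, 1e4, 1e4))
  lu <- landUseLayer(list(big, half), c("industrial", "commercial"))
  # disc fully inside a polygon
  expect_equal(landUseAreaInBuffer(lu, "industrial", c(0, 0), 50), pi * 2500,
               tolerance = 1e-9)
  # half-plane edge through the centre: half the disc
  expect_equal(landUseAreaInBuffer(lu, "commercial", c(0, 0), 50),
               pi * 2500 / 2, tolerance = 1e-9)
  # no polygons of the class near the site
  expect_equal(landUseAreaInBuffer(lu, "nature", c(0, 0), 50), 0)
  # Monte-Carlo cross-check on a non-convex polygon
  poly <- cbind(c(0, 200, 200, 100, 100, 0), c(0, 0, 150, 150, 60, 60))
  luk <- landUseLayer(list(poly), "buildings")
  set.seed(8)
  pts <- cbind(runif(4e5, -150, 250), runif(4e5, -150, 250))
  r <- 120
  inDisc <- (pts[, 1] - 80)^2 + (pts[, 2] - 40)^2 <= r^2
  inPoly <- pts[, 1] >= 0 & pts[, 1] <= 200 & pts[, 2] >= 0 &
    (pts[, 2] <= 60 | (pts[, 1] >= 100 & pts[, 2] <= 150))
  mc <- mean(inDisc & inPoly) * 400^2
  expect_equal(landUseAreaInBuffer(luk, "buildings", c(80, 40), r), mc,
               tolerance = 0.02)
})

test_that("raster buffer means follow the cell-centre rule", {
  uni <- rasterGrid(0, 0, 30, matrix(0.3, 50, 50))
  expect_equal(rasterMeanInBuffer(uni, c(750, 750), 100), 0.3)
  # buffer smaller than one cell: value of the containing cell
  m <- matrix(seq(-0.5, 0.5, length.out = 2500), 50, 50)
  rg <- rasterGrid(0, 0, 30, m)
  expect_equal(rasterMeanInBuffer(rg, c(45, 45), 10), m[2, 2])
  # half 0.0 / half 0.6 split symmetric about the site
  half <- matrix(0, 50, 50); half[, 26:50] <- 0.6
  rh <- rasterGrid(0, 0, 30, half)
  expect_equal(rasterMeanInBuffer(rh, c(750, 750), 200), 0.3, tolerance = 1e-9)
  # missing cells are ignored; all-missing signals
  hna <- matrix(NA_real_, 10, 10)
  expect_error(rasterMeanInBuffer(rasterGrid(0, 0, 30, hna), c(150, 150), 50),
               "no non-missing")
  expect_error(rasterMeanInBuffer(uni, c(1e6, 1e6), 100), "overlap")
})

test_that("buffer statistics scale correctly with the coordinate unit", {
  lay <- smallLayout(seed = 12, nSites = 5)
  rn <- lay$layers$roads
  site <- c(lay$sites$x[1], lay$sites$y[1])
  rn2 <- roadNetwork(lapply(rn@coords, function(m) m * 2), rn@roadClass)
  lu <- lay$layers$landuse
  lu2 <- landUseLayer(lapply(lu@polygons, function(m) m * 2), lu@useClass)
  for (r in c(100, 300)) {
    expect_equal(lineLengthInBuffer(rn2, "small", site * 2, 2 * r),
                 2 * lineLengthInBuffer(rn, "small", site, r),
                 tolerance = 1e-9)
    expect_equal(landUseAreaInBuffer(lu2, "residential", site * 2, 2 * r),
                 4 * landUseAreaInBuffer(lu, "residential", site, r),
                 tolerance = 1e-6)
  }
})

test_that("the candidate grid matches the published variable inventory", {
  cv <- candidateVariables()
  expect_equal(nrow(cv), 105)
  expect_equal(sum(cv$category == "roads"), 51)  # 10 types x 5 radii + 1 dist
  expect_equal(sum(cv$var_type == "hh_density"), 7)
  expect_equal(sum(startsWith(cv$var_type, "landuse_")), 35)
  expect_equal(sum(cv$var_type == "ndvi"), 6)
  expect_setequal(unique(cv$expected_sign), c(1, -1))
  # negative priors exactly for greenness and the quiet land uses
  neg <- cv$name[cv$expected_sign == -1]
  expect_true(all(grepl("^(ndvi_|landuse_(residential|nature)_)", neg)))
})

test_that("feature matrix construction is dense, labelled and permutable", {
  lay <- smallLayout(seed = 4, nSites = 12)
  fm <- buildFeatureMatrix(lay$sites, lay$layers)
  expect_s4_class(fm, "FeatureMatrix")
  expect_lte(nrow(fm), 105)
  expect_equal(ncol(fm), 12)
  expect_false(any(!is.finite(featureValues(fm))))
  expect_true(all(featureValues(fm)[variableData(fm)$unit %in%
                                      c("m", "m2", "1/m2"), ] >= 0))
  expect_true(all(featureValues(fm)[variableData(fm)$unit == "1/m", ] > 0))
  # permuting sites permutes columns only
  perm <- sample(nrow(lay$sites))
  fm2 <- buildFeatureMatrix(lay$sites[perm, ], lay$layers)
  expect_equal(featureValues(fm2), featureValues(fm)[, perm])
  # buffer monotonicity of length/count/area variables within each type
  vd <- as.data.frame(variableData(fm))
  X <- featureValues(fm)
  for (tp in unique(vd$var_type[vd$unit %in% c("m", "m2")])) {
    rows <- vd$name[vd$var_type == tp][order(vd$buffer_m[vd$var_type == tp])]
    if (length(rows) < 2) next
    expect_true(all(apply(X[rows, ], 2, function(z) all(diff(z) >= -1e-9))))
  }
})

test_that("variables from empty or absent layers are dropped with a warning", {
  lay <- smallLayout(seed = 5, nSites = 6)
  lay$layers$points$railway_active <- pointFeatureSet("railway_active")
  lay$layers$points$railway_any <- pointFeatureSet("railway_any")
  expect_warning(fm <- buildFeatureMatrix(lay$sites, lay$layers),
                 "railway")
  expect_false(any(grepl("railway", rownames(fm))))
  # an empty household layer keeps its columns, all zero
  lay2 <- smallLayout(seed = 5, nSites = 6)
  lay2$layers$households <- householdLayer()
  fm2 <- buildFeatureMatrix(lay2$sites, lay2$layers)
  expect_true(all(featureValues(fm2)[paste0("hh_density_",
                                            c(25, 100, 1000)), ] == 0))
})
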