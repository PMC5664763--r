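# Shared fixtures, built in code.

testWindow <- analysisWindow()

# A constant-level series spanning the whole window.
constantSeries <- function(level = 60, n = 432000, siteId = "S1",
                           window = testWindow) {
  soundLevelSeries(siteId, windowStart(window) + seq_len(n) - 1,
                   rep(level, n))
}

# Wrap a plain sites x variables matrix as a FeatureMatrix; every column
# is its own variable type (no buffers) unless metadata is supplied.
plainFeatureMatrix <- function(X, signs = rep(1, ncol(X)),
                               types = colnames(X),
                               buffers = rep(NA_real_, ncol(X))) {
  vars <- data.frame(name = colnames(X), category = "synthetic",
                     var_type = types, buffer_m = buffers,
                     expected_sign = signs, unit = "z")
  sites <- data.frame(site_id = sprintf("T%03d", seq_len(nrow(X))),
                      x = seq_len(nrow(X)) * 1000, y = 0, area = "a")
  featureMatrix(t(X), vars, sites)
}

# Independent oracle for the selection procedure: exhaustive best-subset
# search maximizing adjusted R2 over all subsets whose pairwise absolute
# Pearson correlations stay below the threshold; ties broken toward the
# smaller subset, then lexicographically. Deliberately implemented apart
# from the stepwise code path.
bestSubsetOracle <- function(X, y, corrThreshold = 0.7) {
  p <- ncol(X)
  C <- abs(suppressWarnings(stats::cor(X)))
  best <- NULL
  for (k in 0:min(p, nrow(X) - 3L)) {
    for (s in utils::combn(p, k, simplify = FALSE)) {
      if (length(s) > 1L) {
        sub <- C[s, s]
        if (any(sub[upper.tri(sub)] >= corrThreshold)) next
      }
      f <- fitOls(X, y, colnames(X)[s])
      sc <- f@adjR2
      if (is.null(best) || sc > best$sc + 1e-12 ||
          (abs(sc - best$sc) <= 1e-12 && length(s) < length(best$s)))
        best <- list(sc = sc, s = s)
    }
  }
  sort(colnames(X)[best$s])
}

# Small layout for GIS tests (fast to generate).
smallLayout <- function(seed = 7, nSites = 25)
  generateLayout(layoutConfig(nSites = nSites, seed = seed))
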