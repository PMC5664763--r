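# Supervised stepwise selection.

test_that("OLS fit recovers exact linear structure and flags collinearity", {
  set.seed(21)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  fm <- plainFeatureMatrix(X)
  y <- 5 + 2 * X[, "a"]
  f <- fitOls(fm, y, "a")
  expect_equal(f@r2, 1, tolerance = 1e-12)
  expect_equal(unname(f@coefficients), c(5, 2), tolerance = 1e-10)
  expect_lte(f@adjR2, f@r2)
  expect_equal(sum(f@residuals), 0, tolerance = 1e-9)
  expect_equal(var(f@fitted) / var(y), f@r2, tolerance = 1e-12)
  # pure noise: slope within 3 SE of zero, R2 near 0
  set.seed(22)
  Xn <- matrix(rnorm(1000), 1000, 1, dimnames = list(NULL, "n1"))
  yn <- rnorm(1000)
  fn <- fitOls(plainFeatureMatrix(Xn), yn, "n1")
  expect_lt(fn@r2, 0.02)
  expect_lt(abs(fn@coefficients["n1"]) / fn@se["n1"], 3)
  # duplicated columns are a rank-deficiency error naming the culprit
  X2 <- cbind(a = X[, "a"], dup = X[, "a"])
  expect_error(fitOls(plainFeatureMatrix(X2), y), "collinear.*dup|dup.*collinear")
})

test_that("the univariate screen records slope, R2 and sign agreement", {
  set.seed(31)
  y <- rnorm(80, 60, 4)
  X <- cbind(same = y, neg = -y, noise = rnorm(80))
  fm <- plainFeatureMatrix(X, signs = c(1, 1, 1))
  sc <- univariateScreen(fm, y)
  expect_equal(sc$r2[sc$name == "same"], 1, tolerance = 1e-12)
  expect_true(sc$sign_ok[sc$name == "same"])
  # a negated copy explains everything but with the wrong sign
  expect_equal(sc$r2[sc$name == "neg"], 1, tolerance = 1e-12)
  expect_false(sc$sign_ok[sc$name == "neg"])
  expect_lt(sc$r2[sc$name == "noise"], 0.1)
})

test_that("best-buffer choice is sign-constrained with smallest-buffer ties", {
  sc <- data.frame(
    name = c("t_25", "t_200", "t_500", "u_50", "u_100", "w_25"),
    var_type = c("t", "t", "t", "u", "u", "w"),
    buffer_m = c(25, 200, 500, 50, 100, 25),
    expected_sign = 1,
    coefficient = c(1, 1, -1, 1, 1, -2),
    r2 = c(0.05, 0.12, 0.30, 0.08, 0.08, 0.9),
    sign_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  best <- selectBestBuffer(sc)
  # highest correctly-signed R2 wins even when a wrong-signed buffer is higher
  expect_equal(best$name[best$var_type == "t"], "t_200")
  # exact tie resolved toward the smaller buffer
  expect_equal(best$name[best$var_type == "u"], "u_50")
  # a type with no correctly-signed buffer disappears
  expect_false("w" %in% best$var_type)
  expect_true("w" %in% attr(best, "dropped_types"))
})

test_that("forward selection applies the correlation and gain gates", {
  set.seed(41)
  n <- 120
  a <- rnorm(n)
  b <- rnorm(n)
  aTwin <- a + rnorm(n, 0, 0.2)       # r ~ 0.98 with a
  noise <- rnorm(n)
  y <- 3 * a + 2 * b + rnorm(n, 0, 0.5)
  X <- cbind(a = a, atwin = aTwin, b = b, noise = noise)
  fm <- plainFeatureMatrix(X)
  sc <- univariateScreen(fm, y)
  fw <- forwardSelection(fm, sc, y)
  expect_true(all(c("a", "b") %in% fw$included))
  expect_false("atwin" %in% fw$included)
  ev <- fw$trace
  expect_equal(ev$event[ev$variable == "atwin"], "rejected_correlation")
  # accepted steps strictly increase adjusted R2
  acc <- ev[ev$event == "added", ]
  expect_true(all(acc$adj_r2_after > acc$adj_r2_before))
})

test_that("backward pruning removes worst p-values one by one", {
  set.seed(51)
  n <- 150
  X <- cbind(s1 = rnorm(n), s2 = rnorm(n), junk = rnorm(n))
  y <- 2 * X[, "s1"] - 1.5 * X[, "s2"] + rnorm(n)
  fm <- plainFeatureMatrix(X, signs = c(1, -1, 1))
  bp <- backwardPrune(fm, c("s1", "s2", "junk"), y)
  expect_setequal(bp$included, c("s1", "s2"))
  expect_equal(bp$trace$event, "removed_pvalue")
  expect_true(all(bp$fit@pValues[bp$included] <= 0.2))
  # a model already satisfying the rule is untouched
  bp2 <- backwardPrune(fm, c("s1", "s2"), y)
  expect_equal(nrow(bp2$trace), 0)
  expect_setequal(bp2$included, c("s1", "s2"))
})

test_that("the challenge step swaps in a better buffer of the same type", {
  set.seed(61)
  n <- 150
  true200 <- rnorm(n)
  proxy50 <- true200 + rnorm(n, 0, 1.2)   # same type, noisier buffer
  other <- rnorm(n)
  y <- 2 * true200 + other + rnorm(n, 0, 0.3)
  X <- cbind(t_50 = proxy50, t_200 = true200, o_1 = other)
  fm <- plainFeatureMatrix(X, signs = c(1, 1, 1),
                           types = c("t", "t", "o"),
                           buffers = c(50, 200, NA))
  ch <- challengeVariables(fm, c("t_50", "o_1"), y)
  expect_setequal(ch$included, c("t_200", "o_1"))
  expect_equal(ch$trace$event, "challenged_swap")
  expect_equal(ch$trace$variable, "t_50")
  expect_equal(ch$trace$detail, "t_200")
  expect_gt(ch$trace$adj_r2_after, ch$trace$adj_r2_before)
  # nothing improves an already-correct model
  ch2 <- challengeVariables(fm, c("t_200", "o_1"), y)
  expect_equal(nrow(ch2$trace), 0)
})

test_that("a challenger violating the correlation gate loses to the runner-up", {
  set.seed(71)
  n <- 200
  kept <- rnorm(n)
  weak <- rnorm(n)
  strongDup <- kept + rnorm(n, 0, 0.1)      # best challenger, but r > 0.7 with kept
  mid <- weak + rnorm(n, 0, 0.8)            # admissible improvement over weak0
  weak0 <- 0.5 * weak + rnorm(n, 0, 1)
  y <- 3 * kept + 2 * weak + rnorm(n, 0, 0.5)
  X <- cbind(kept = kept, weak0 = weak0, dupk = strongDup, mid = mid)
  fm <- plainFeatureMatrix(X)
  ch <- challengeVariables(fm, c("kept", "weak0"), y)
  expect_true("kept" %in% ch$included)
  expect_false("dupk" %in% ch$included)
  expect_true("mid" %in% ch$included)
})

test_that("final augmentation admits at most one variable under the p gate", {
  set.seed(81)
  n <- 150
  a <- rnorm(n); b <- rnorm(n); c2 <- rnorm(n)
  y <- 2 * a + b + 0.8 * c2 + rnorm(n, 0, 0.5)
  X <- cbind(a = a, b = b, held = c2, n1 = rnorm(n))
  fm <- plainFeatureMatrix(X)
  au <- finalAugment(fm, c("a", "b"), y)
  expect_setequal(au$included, c("a", "b", "held"))
  expect_equal(au$trace$event, "augmented")
  expect_lte(au$fit@pValues["held"], 0.2)
  # candidates failing the p gate are not kept even with an adj-R2 gain
  set.seed(82)
  yb <- 2 * a + rnorm(n, 0, 1)
  Xb <- cbind(a = a, w = rnorm(n))
  fmb <- plainFeatureMatrix(Xb)
  f0 <- fitOls(fmb, yb, c("a", "w"))
  if (f0@pValues["w"] > 0.2) {
    aub <- finalAugment(fmb, "a", yb)
    expect_equal(aub$included, "a")
  }
})

test_that("buildLUR is deterministic and satisfies its exit invariants", {
  lay <- smallLayout(seed = 9, nSites = 60)
  fm <- buildFeatureMatrix(lay$sites, lay$layers)
  y <- generateResponse(fm, truthModel(sigma = 2), seed = 99)
  m1 <- buildLUR(fm, y)
  m2 <- buildLUR(fm, y)
  expect_identical(selectionTrace(m1), selectionTrace(m2))
  expect_identical(coef(m1), coef(m2))
  vars <- selectedVariables(m1)
  expect_gt(length(vars), 0)
  # pairwise correlation gate holds on the final model
  X <- t(featureValues(fm))[, vars, drop = FALSE]
  C <- abs(cor(X))
  expect_true(all(C[upper.tri(C)] < 0.7))
  # accepted forward/challenge/augment steps strictly increase adjusted R2
  tr <- selectionTrace(m1)
  acc <- tr[tr$event %in% c("added", "challenged_swap", "augmented"), ]
  expect_true(all(acc$adj_r2_after > acc$adj_r2_before))
  # refitting the selected set reproduces the reported fit (trace replay)
  refit <- fitOls(fm, y, vars)
  expect_equal(coef(refit), coef(m1), tolerance = 1e-12)
  expect_equal(adjustedR2(refit), adjustedR2(m1), tolerance = 1e-12)
})

test_that("all p-values satisfy the threshold right after pruning", {
  lay <- smallLayout(seed = 14, nSites = 80)
  fm <- buildFeatureMatrix(lay$sites, lay$layers)
  y <- generateResponse(fm, truthModel(sigma = 3), seed = 5)
  sc <- selectBestBuffer(univariateScreen(fm, y))
  fw <- forwardSelection(fm, sc, y)
  bp <- backwardPrune(fm, fw$included, y)
  if (length(bp$included))
    expect_true(all(bp$fit@pValues[bp$included] <= 0.2))
})

test_that("a pure-noise response yields an empty or near-empty model", {
  lay <- smallLayout(seed = 10, nSites = 60)
  fm <- buildFeatureMatrix(lay$sites, lay$layers)
  y <- generateResponse(fm, truthModel(beta = numeric(0) , sigma = 4.7),
                        seed = 17)
  m <- buildLUR(fm, y)
  expect_lte(length(selectedVariables(m)), 3)
  expect_lt(adjustedR2(m), 0.25)
})

test_that("greedy selection matches exhaustive best-subset search at sigma = 0", {
  set.seed(42)
  for (i in 1:20) {
    n <- 60; p <- 6
    X <- matrix(rnorm(n * p), n, p) + 0.3 * rnorm(n)
    colnames(X) <- sprintf("v%02d", 1:p)
    beta <- c(2, -1.5, 1, 0, 0, 0)
    signs <- ifelse(beta != 0, sign(beta), sample(c(-1, 1), p, TRUE))
    y <- drop(X %*% beta)
    fm <- plainFeatureMatrix(X, signs = signs)
    sel <- sort(selectedVariables(buildLUR(fm, y)))
    expect_identical(sel, bestSubsetOracle(X, y))
  }
})

test_that("model JSON round trip preserves fit and trace", {
  lay <- smallLayout(seed = 9, nSites = 60)
  fm <- buildFeatureMatrix(lay$sites, lay$layers)
  y <- generateResponse(fm, truthModel(sigma = 2), seed = 99)
  m <- buildLUR(fm, y)
  f <- tempfile(fileext = ".json")
  writeModelJson(m, f)
  m2 <- readModelJson(f)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(adjustedR2(m2), adjustedR2(m), tolerance = 1e-12)
  expect_equal(selectedVariables(m2), selectedVariables(m))
  expect_equal(nrow(selectionTrace(m2)), nrow(selectionTrace(m)))
  p1 <- predict(m, fm); p2 <- predict(m2, fm)
  expect_equal(p2, p1, tolerance = 1e-10)
  unlink(f)
})
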