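test_that("rotate90ccw implements the counter-clockwise coordinate map", {
  m <- matrix(c("a", "c", "b", "d"), 2, 2)  # rows (a,b),(c,d)
  expect_identical(rotate90ccw(m), matrix(c("b", "a", "d", "c"), 2, 2))
  ## four rotations are the identity, also for non-square input
  r <- matrix(rnorm(12), 3, 4)
  expect_identical(rotate90ccw(rotate90ccw(rotate90ccw(rotate90ccw(r)))), r)
  expect_identical(dim(rotate90ccw(r)), c(4L, 3L))
  ## 28 x 28 stays 28 x 28 and flattens to length 784
  img <- matrix(runif(784), 28, 28)
  expect_identical(dim(rotate90ccw(img)), c(28L, 28L))
  expect_length(as.vector(rotate90ccw(img)), 784L)
  ## coordinate contract: input (r, c) -> output (w + 1 - c, r), 1-based
  h <- 3; w <- 4
  x <- matrix(seq_len(h * w), h, w)
  y <- rotate90ccw(x)
  for (r in seq_len(h)) for (cc in seq_len(w))
    expect_equal(y[w + 1 - cc, r], x[r, cc])
  expect_error(rotate90ccw(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("random erasing corrupts one rectangle of the requested area", {
  img <- matrix(1, 4, 4)
  ## degenerate zero-area range leaves the image unchanged
  expect_identical(applyRandomErasing(img, c(0, 0)), img)
  expect_error(applyRandomErasing(img, c(-0.1, 0.5)), "areaFractionRange")
  expect_error(applyRandomErasing(img, c(0.2, 1)), "areaFractionRange")
  ## fixed seed, 4x4 ones, fraction 0.25 -> exactly 4 pixels erased
  out <- fuseAE:::withSeed(1, applyRandomErasing(img, c(0.25, 0.25)))
  expect_equal(sum(out == 0), 4)
  expect_equal(sum(out == 1), 12)
  ## across seeds the patch is a contiguous rectangle of ~4 pixels
  ## (3 or 4 after integer rounding of the drawn aspect ratio)
  for (s in 1:25) {
    out <- fuseAE:::withSeed(s, applyRandomErasing(img, c(0.25, 0.25)))
    expect_true(sum(out == 0) %in% c(3L, 4L))
  }
  ## intensities stay in [0, 1] for any fill value in [0, 1]
  noisy <- matrix(runif(64), 8, 8)
  out <- applyRandomErasing(noisy, c(0.1, 0.3), fillValue = 0.7)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("gaussian noise matches its truncated half-normal magnitude", {
  img <- matrix(0.5, 100, 100)
  expect_identical(applyGaussianNoise(img, 0), img)
  expect_error(applyGaussianNoise(img, -0.1), "sigma")
  out <- fuseAE:::withSeed(7, applyGaussianNoise(img, 0.3))
  expect_true(all(out >= 0 & out <= 1))
  ## closed-form mean absolute perturbation of clipped N(0, sigma):
  ## E[min(|Z|, c)] with c = 0.5 the distance to both clip boundaries
  s <- 0.3; cc <- 0.5
  expected <- s * sqrt(2 / pi) * (1 - exp(-cc^2 / (2 * s^2))) +
    2 * cc * (1 - pnorm(cc / s))
  expect_equal(mean(abs(out - 0.5)), expected, tolerance = 0.05)
})

test_that("two-view construction pairs the image with its rotation", {
  g <- makeSyntheticDigits(nPerClass = 4, nClasses = 3, imageSize = 12,
                           seed = 2)
  tv <- makeTwoView(g$images, g$labels, "none", seed = 5)
  ## without noise, view 2 is exactly the flattened rotation of view 1
  for (i in c(1L, 7L)) {
    img <- matrix(view1(tv)[i, ], 12, 12)
    expect_equal(view2(tv)[i, ], as.vector(rotate90ccw(img)))
  }
  ## pure function of the seed
  tvA <- makeTwoView(g$images, g$labels, "erasing", seed = 9)
  tvB <- makeTwoView(g$images, g$labels, "erasing", seed = 9)
  expect_identical(view1(tvA), view1(tvB))
  expect_identical(view2(tvA), view2(tvB))
  ## erasing draws independent patches per view: the erased masks differ
  ## from what rotating view 1's mask would give
  i <- 1L
  m1 <- matrix(view1(tvA)[i, ] == 0, 12, 12)
  m2 <- matrix(view2(tvA)[i, ] == 0, 12, 12)
  expect_false(identical(rotate90ccw(m1), m2))
  expect_error(makeTwoView(g$images, g$labels, "speckle"), "arg")
})

test_that("synthetic glyphs are balanced, deterministic and separable", {
  g <- makeSyntheticDigits(nPerClass = 10, nClasses = 10, seed = 4)
  expect_equal(dim(g$images), c(100, 28, 28))
  expect_equal(as.vector(table(g$labels)), rep(10L, 10))
  expect_true(all(g$images >= 0 & g$images <= 1))
  g2 <- makeSyntheticDigits(nPerClass = 10, nClasses = 10, seed = 4)
  expect_identical(g$images, g2$images)
  expect_error(makeSyntheticDigits(5, imageSize = 6), "imageSize")
  expect_error(makeSyntheticDigits(5, nClasses = 11), "nClasses")
  ## a linear (nearest-centroid) classifier on clean flattened glyphs
  ## exceeds 0.9 held-out accuracy
  g <- makeSyntheticDigits(nPerClass = 30, nClasses = 10, seed = 11)
  X <- t(apply(g$images, 1, as.vector))
  tr <- unlist(lapply(split(seq_len(300), g$labels), head, 20))
  te <- setdiff(seq_len(300), tr)
  cent <- sapply(0:9, function(cl) colMeans(X[tr[g$labels[tr] == cl], ]))
  d <- sapply(seq_len(10), function(j)
    rowSums(sweep(X[te, ], 2, cent[, j])^2))
  pred <- max.col(-d, ties.method = "first") - 1L
  expect_gt(mean(pred == g$labels[te]), 0.9)
})

test_that("the omics survival generator honors its contract", {
  ## null effects: all true risks equal
  simNull <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = 60, effectShared = 0, effectUnique = 0, seed = 3))
  expect_equal(var(simNull$trueRisk), 0)
  ## no censoring: every sample has an observed event
  sim0 <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = 80, censoringFraction = 0, seed = 3))
  expect_true(all(eventIndicator(sim0$survival) == 1L))
  ## censoring calibration within +/- 0.05 at n = 600
  sim <- simulateOmicsSurvival(syntheticOmicsConfig(nSamples = 600,
                                                    seed = 17))
  expect_lt(abs(mean(eventIndicator(sim$survival) == 0L) - 0.3), 0.05)
  ## matrices are [0, 1]-scaled with no missing values; deterministic
  v <- omicsValues(sim$omics[[1]])
  expect_true(all(is.finite(v)) && min(v) >= 0 && max(v) <= 1)
  sim2 <- simulateOmicsSurvival(syntheticOmicsConfig(nSamples = 600,
                                                     seed = 17))
  expect_identical(omicsValues(sim$omics[[2]]), omicsValues(sim2$omics[[2]]))
  expect_error(simulateOmicsSurvival(syntheticOmicsConfig(
    featuresPerModality = 50, nModalities = 2)), "shorter")
  ## oracle property: positive effects give informative true risk
  expect_gt(concordanceIndex(sim$trueRisk, survTimes(sim$survival),
                             eventIndicator(sim$survival)), 0.5)
})

test_that("shared-signal modalities correlate above permuted controls", {
  sim <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = 200, effectUnique = 0, seed = 5))
  p1 <- prcomp(omicsValues(sim$omics[[1]]))$x[, 1:5]
  p2 <- prcomp(omicsValues(sim$omics[[2]]))$x[, 1:5]
  ccShared <- cancor(p1, p2)$cor[1]
  ccPerm <- fuseAE:::withSeed(9, cancor(p1, p2[sample(200), ])$cor[1])
  expect_gt(ccShared, ccPerm)
  expect_gt(ccShared, 0.8)
})

test_that("omics and survival CSV round-trips preserve the data", {
  sim <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = 12, featuresPerModality = c(6, 4), seed = 8))
  f1 <- tempfile(fileext = ".csv")
  writeOmicsMatrix(sim$omics[[1]], f1)
  back <- readOmicsMatrix(f1, modality = modality(sim$omics[[1]]))
  expect_equal(omicsValues(back), omicsValues(sim$omics[[1]]))
  expect_identical(sampleIds(back), sampleIds(sim$omics[[1]]))
  f2 <- tempfile(fileext = ".csv")
  writeSurvivalData(sim$survival, f2)
  sback <- readSurvivalData(f2)
  expect_equal(survTimes(sback), survTimes(sim$survival))
  expect_identical(eventIndicator(sback), eventIndicator(sim$survival))
})
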