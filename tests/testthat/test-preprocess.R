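om <- function(v, mod = "GeneExp") OmicsMatrix(v, modality = mod)

test_that("missing-feature removal is column-wise only", {
  v <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:5)))
  expect_equal(omicsValues(dropMissingFeatures(om(v))), v)
  v2 <- v; v2[1, 2] <- NA; v2[3, 4] <- NA
  out <- dropMissingFeatures(om(v2))
  expect_identical(featureIds(out), c("f1", "f3", "f5"))
  expect_equal(length(sampleIds(out)), 4L)  # samples never dropped
  v3 <- v; v3[1, ] <- NA
  expect_error(dropMissingFeatures(om(v3)), "all features")
})

test_that("log2(X+1) transforms expression values", {
  v <- matrix(c(0, 1, 3, 7), 1, 4)
  expect_equal(as.vector(omicsValues(log2Transform(om(v)))), c(0, 1, 2, 3))
  expect_error(log2Transform(om(matrix(-1, 1, 1))), "non-negative")
})

test_that("min-max scaling uses training statistics only", {
  tr <- om(matrix(c(2, 4, 6), 3, 1))
  t1 <- minmaxFit(tr)
  expect_equal(as.vector(omicsValues(applyTransform(t1, tr))),
               c(0, 0.5, 1))
  ## constant training feature maps to 0
  t2 <- minmaxFit(om(matrix(5, 3, 1)))
  expect_equal(as.vector(omicsValues(applyTransform(
    t2, om(matrix(c(5, 7), 2, 1))))), c(0, 0))
  ## out-of-range test value kept by default, clipped on request
  test8 <- om(matrix(8, 1, 1))
  expect_equal(as.vector(omicsValues(applyTransform(t1, test8))), 1.5)
  expect_equal(as.vector(omicsValues(applyTransform(t1, test8,
                                                    clip = TRUE))), 1)
  ## training matrix itself always lands exactly in [0, 1]
  set.seed(3)
  big <- om(matrix(rnorm(200), 20, 10))
  scaled <- omicsValues(applyTransform(minmaxFit(big), big))
  expect_equal(range(scaled), c(0, 1))
  expect_error(applyTransform(t1, om(matrix(1, 1, 2))), "feature ids")
})

test_that("variance selection equals a brute-force sort with index ties", {
  tr <- om(matrix(c(1, 1.1, 0.9, 0, 3, -3, 0.5, 1.5, 1), 3, 3))
  sel <- varianceSelectFit(tr, 1)
  expect_equal(sel@params$indices, 2L)       # the high-variance feature
  expect_error(varianceSelectFit(tr, 0), "positive")
  expect_error(varianceSelectFit(tr, 9), "exceeds")
  ## constant features are never selected while better ones remain
  v <- cbind(const = rep(1, 10), a = rnorm(10), b = rnorm(10))
  expect_false(1L %in% varianceSelectFit(om(v), 2)@params$indices)
  ## oracle: full sort of variances on random matrices
  for (rep in 1:20) {
    set.seed(rep)
    v <- matrix(rnorm(50 * 20), 50, 20)
    v[, 5] <- v[, 7]  # force a variance tie
    sel <- varianceSelectFit(om(v), 8)@params$indices
    vars <- apply(v, 2, var)
    oracle <- sort(order(-vars, seq_along(vars))[1:8])
    expect_identical(sel, oracle)
  }
})

test_that("PCA centers on the training mean and orders components", {
  ## rank-1 data: first component explains everything
  line <- om(cbind(1:10, 2 * (1:10)))
  p1 <- pcaFit(line, 1)
  expect_equal(p1@params$explainedVarianceRatio[1], 1)
  ## projecting the training mean gives the zero vector
  mu <- om(matrix(colMeans(omicsValues(line)), 1, 2,
                  dimnames = list("m", featureIds(line))))
  expect_equal(as.vector(omicsValues(applyTransform(p1, mu))), 0)
  ## hand-computed 2x2 covariance [[2,1],[1,2]]: eigenvalues 3 and 1
  a <- 1.5; b <- sqrt(0.75)
  pts <- rbind(c(a, a), c(-a, -a), c(b, -b), c(-b, b))
  expect_equal(cov(pts), matrix(c(2, 1, 1, 2), 2, 2))
  pf <- pcaFit(om(pts), 2)
  expect_equal(pf@params$explainedVarianceRatio, c(0.75, 0.25))
  ## sign convention: largest-magnitude loading is positive
  expect_true(all(apply(pf@params$rotation, 2,
                        function(r) r[which.max(abs(r))] > 0)))
  expect_error(pcaFit(om(pts), 4), "nComponents")
})

test_that("fitted transforms survive the JSON sidecar round-trip", {
  set.seed(5)
  tr <- om(matrix(rnorm(60), 10, 6))
  newdata <- om(`colnames<-`(matrix(rnorm(30), 5, 6), featureIds(tr)))
  for (tf in list(minmaxFit(tr), varianceSelectFit(tr, 3), pcaFit(tr, 2))) {
    f <- tempfile(fileext = ".json")
    writeTransform(tf, f)
    tf2 <- readTransform(f)
    expect_equal(omicsValues(applyTransform(tf2, newdata)),
                 omicsValues(applyTransform(tf, newdata)))
  }
})

test_that("stratified folds partition samples and preserve strata", {
  strata <- rep(0:1, each = 50)
  folds <- stratifiedFolds(strata, seed = 1)
  tests <- lapply(folds, function(f) f@testIdx)
  expect_equal(sort(unlist(tests)), 1:100)      # test sets partition
  expect_true(all(lengths(tests) == 25))
  for (f in folds) {
    expect_equal(length(f@trainIdx), 60)
    expect_equal(length(f@valIdx), 15)
    ## pairwise disjoint within the fold
    expect_equal(length(intersect(f@trainIdx, f@testIdx)), 0)
    expect_equal(length(intersect(f@trainIdx, f@valIdx)), 0)
    ## stratum balance within each set
    for (ix in list(f@trainIdx, f@valIdx, f@testIdx))
      expect_lte(abs(sum(strata[ix] == 0) - sum(strata[ix] == 1)), 1)
  }
  expect_identical(stratifiedFolds(strata, seed = 1), folds)  # deterministic
  expect_error(stratifiedFolds(c(rep(0, 97), rep(1, 3))), "fewer samples")
  expect_error(stratifiedFolds(strata, fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("event fraction is preserved across splits of a 40% simulation", {
  set.seed(21)
  ev <- rbinom(300, 1, 0.4)
  folds <- stratifiedFolds(ev, seed = 2)
  for (f in folds) {
    for (ix in list(f@trainIdx, f@valIdx, f@testIdx))
      expect_lte(abs(mean(ev[ix]) - mean(ev)), 0.05)
  }
})

test_that("transforms never see validation or test rows", {
  set.seed(9)
  v <- matrix(rnorm(200), 20, 10)
  trainIdx <- 1:12
  tfTrain <- minmaxFit(om(v[trainIdx, , drop = FALSE]))
  tfAll <- minmaxFit(om(v))
  ## fitting on all rows gives different parameters...
  expect_false(isTRUE(all.equal(tfTrain@params$lo, tfAll@params$lo)))
  ## ...and applying the train-fitted transform uses only train statistics
  applied <- omicsValues(applyTransform(
    tfTrain, om(`colnames<-`(v[13:20, ], featureIds(om(v[trainIdx, ]))))))
  expected <- sweep(sweep(v[13:20, ], 2, apply(v[trainIdx, ], 2, min)),
                    2, apply(v[trainIdx, ], 2, max) -
                       apply(v[trainIdx, ], 2, min), "/")
  expect_equal(unname(applied), unname(expected))
})
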