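toy <- makeToyClassification(n = 40, p = 8, seed = 3)
spToy <- networkSpec(8, hiddenDim = 3)

test_that("zero training epochs leave the initialization untouched", {
  cfg <- trainConfig("classification", epochs = 0L, seed = 7)
  b0 <- trainSingle(spToy, toy$x, toy$y, cfg)
  expect_equal(nrow(b0@trace), 0L)
  ## white-box init-order contract: autoencoder params then head params,
  ## drawn from the config seed
  expected <- fuseAE:::withSeed(7, {
    p <- initAutoencoderParams(spToy)
    h <- initHeadParams(3, "classification", nClasses = 2L)
    list(p = p, h = h)
  })
  expect_equal(b0@params$modalities[[1]]$encoder, expected$p$encoder)
  expect_equal(b0@params$modalities[[1]]$decoder, expected$p$decoder)
  expect_equal(b0@params$head, expected$h)
  ## same for a CrossAE schedule with (0, 0, 0) step epochs
  cfgx <- trainConfig("classification", seed = 7,
                      epochsPerCrossStep = c(0L, 0L, 0L))
  bx <- trainCross(list(spToy, spToy), list(toy$x, toy$x), toy$y, cfgx)
  expect_equal(bx@params$modalities[[1]]$encoder, expected$p$encoder)
  expect_equal(nrow(bx@trace), 0L)
})

test_that("training separates linearly separable toy data", {
  cfg <- trainConfig("classification", epochs = 200, seed = 1)
  b <- trainSingle(networkSpec(10, hiddenDim = 4),
                   makeToyClassification(50, 10, 1)$x,
                   makeToyClassification(50, 10, 1)$y, cfg)
  pred <- max.col(predictBundle(b, makeToyClassification(50, 10, 1)$x),
                  ties.method = "first") - 1L
  expect_equal(mean(pred == makeToyClassification(50, 10, 1)$y), 1)
  ## reconstruction improves over initialization
  expect_lt(b@trace$recon[nrow(b@trace)], b@trace$recon[1])
  ## task loss improves too
  expect_lt(b@trace$task[nrow(b@trace)], b@trace$task[1])
})

test_that("training is a pure function of config and seed", {
  cfg <- trainConfig("classification", epochs = 8, seed = 5)
  b1 <- trainSingle(spToy, toy$x, toy$y, cfg)
  b2 <- trainSingle(spToy, toy$x, toy$y, cfg)
  expect_identical(b1@trace, b2@trace)
  expect_equal(b1@params, b2@params)
})

test_that("concat on a single modality reduces exactly to single", {
  cfg <- trainConfig("classification", epochs = 6, seed = 2)
  bs <- trainSingle(spToy, toy$x, toy$y, cfg)
  bc <- trainConcat(list(spToy), list(toy$x), toy$y, cfg)
  expect_identical(bc@trace, bs@trace)
  expect_equal(bc@params, bs@params)
  expect_error(trainCross(list(spToy), list(toy$x), toy$y, cfg), ">= 2")
})

test_that("concat training lowers both per-modality reconstructions", {
  set.seed(11)
  x2 <- toy$x[, sample(8)]
  cfg <- trainConfig("classification", epochs = 15, seed = 4)
  b <- trainConcat(list(spToy, spToy), list(toy$x, x2), toy$y, cfg)
  expect_lt(b@trace$recon[nrow(b@trace)], b@trace$recon[1])
  per <- multiReconLoss(
    list(toy$x, x2),
    list(aeDecode(spToy, b@params$modalities[[1]],
                  encodeBundle(b, list(toy$x, x2))[[1]]),
         aeDecode(spToy, b@params$modalities[[2]],
                  encodeBundle(b, list(toy$x, x2))[[2]])))
  expect_lt(per, b@trace$recon[1])
})

test_that("the cross-reconstruction phase aligns paired latents", {
  sim <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = 120, featuresPerModality = c(30, 30), effectUnique = 0,
    noiseSd = 0.1, seed = 6))
  xs <- lapply(sim$omics, omicsValues)
  sp <- networkSpec(30, hiddenDim = 5)
  mk <- function(steps) trainConfig("survival", batchSize = 32,
                                    seed = 3, epochsPerCrossStep = steps)
  bStep1 <- trainCross(list(sp, sp), xs, sim$survival, mk(c(15L, 0L, 0L)))
  bStep2 <- trainCross(list(sp, sp), xs, sim$survival, mk(c(15L, 15L, 0L)))
  d1 <- pairedHiddenDistance(encodeBundle(bStep1, xs)[[1]],
                             encodeBundle(bStep1, xs)[[2]])$mean
  d2 <- pairedHiddenDistance(encodeBundle(bStep2, xs)[[1]],
                             encodeBundle(bStep2, xs)[[2]])$mean
  expect_lt(d2, d1)
  ## the cross loss itself decreases within step 2
  crossTrace <- bStep2@trace[bStep2@trace$phase == "cross", "cross"]
  expect_lt(crossTrace[length(crossTrace)], crossTrace[1])
})

test_that("survival training requires events and tracks the C-index", {
  sim <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = 100, featuresPerModality = c(20, 20), seed = 9))
  x <- omicsValues(sim$omics[[1]])
  sp <- networkSpec(20, hiddenDim = 4)
  cfg <- trainConfig("survival", batchSize = 32, epochs = 4, seed = 2)
  b <- trainSingle(sp, x[1:70, ], sim$survival[1:70], cfg,
                   valX = x[71:100, ], valOutcome = sim$survival[71:100])
  expect_true(all(is.finite(b@trace$val)))
  expect_true(all(b@trace$val >= 0 & b@trace$val <= 1))
  ## checkpoint selection uses the validation metric only
  expect_equal(attr(b@trace, "bestEpoch"), which.max(b@trace$val))
  ## all-censored data refuse to train
  dead <- SurvivalData(sprintf("c%d", 1:30), rexp(30) + 1, rep(0, 30))
  expect_error(trainSingle(sp, x[1:30, ], dead, cfg), "no events")
})

test_that("cross-validation aggregates one test metric per fold", {
  toyBig <- makeToyClassification(n = 80, p = 10, seed = 12)
  omx <- list(OmicsMatrix(toyBig$x, modality = "m1"))
  cfg <- trainConfig("classification", epochs = 4, seed = 1)
  cv <- runCrossValidation(omx, toyBig$y, integration = "single",
                           featureMethod = "none", latentDim = 3,
                           config = cfg, seed = 2)
  expect_length(foldValues(cv$reports$accuracy), 4L)
  expect_equal(nrow(cv$perFold), 4L)
  expect_named(cv$reports, c("accuracy", "weighted_precision",
                             "weighted_recall"))
  ## deterministic end to end
  cv2 <- runCrossValidation(omx, toyBig$y, integration = "single",
                            featureMethod = "none", latentDim = 3,
                            config = cfg, seed = 2)
  expect_identical(cv$perFold, cv2$perFold)
  expect_error(runCrossValidation(omx, toyBig$y, integration = "single",
                                  featureMethod = "none", latentDim = 3,
                                  config = cfg, nFolds = 1L), "nFolds")
})

test_that("mismatched sample ids across modalities are refused by name", {
  sim <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = 40, featuresPerModality = c(10, 10), seed = 2))
  bad <- OmicsMatrix(omicsValues(sim$omics[[2]]),
                     sampleIds = rev(sampleIds(sim$omics[[2]])),
                     modality = "Mod2")
  expect_error(
    runCrossValidation(list(sim$omics[[1]], bad), sim$survival,
                       integration = "concat", featureMethod = "none",
                       latentDim = 3,
                       config = trainConfig("survival", epochs = 1)),
    "Mod2")
})

test_that("reports format as mean plus-minus sd at three decimals", {
  d <- 0.031 * sqrt(3) / 2
  rep <- new("MetricsReport", metricName = "cindex", endpoint = "survival",
             foldValues = 0.641 + c(-d, -d, d, d))
  expect_identical(formatMetricsReport(rep), "0.641 ± 0.031")
  expect_match(formatMetricsReport(rep), "^\\d\\.\\d{3} ± \\d\\.\\d{3}$")
})
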