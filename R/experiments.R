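#' Scaled two-view integration experiment
#'
#' The simulation protocol for validating the integration principles on
#' paired image views: glyph images are corrupted independently in each
#' view (original and 90-degree rotation), models are trained on a
#' stratified split and test accuracy is reported per model. With
#' random erasing the two views lose different regions, so
#' complementary (ConcatAE) integration should beat either view alone;
#' with pixel-wise Gaussian noise both views are globally corrupted and
#' consensus (CrossAE) integration is expected to lead.
#'
#' @param noiseKind `"erasing"` or `"gaussian"`
#' @param seeds integer vector; the experiment is repeated per seed and
#'   all randomness (data, corruption, split, training) derives from it
#' @param models subset of `c("single1", "single2", "concat", "cross")`
#' @param nPerClass images per class (default 250: 200 train + 50 test
#'   per class)
#' @param trainPerClass training images per class
#' @param epochs training epochs (CrossAE phases get
#'   `epochs/2, epochs/2, epochs`)
#' @param latentDim latent dimension per view
#' @return data.frame with one row per seed and columns per model's
#'   test accuracy
#' @export
twoViewExperiment <- function(noiseKind, seeds = 1:3,
                              models = c("single1", "single2", "concat",
                                         "cross"),
                              nPerClass = 250L, trainPerClass = 200L,
                              epochs = 50L, latentDim = 16L) {
  rows <- lapply(seeds, function(seed) {
    g <- makeSyntheticDigits(nPerClass, 10L, seed = seed)
    tv <- makeTwoView(g$images, g$labels, noiseKind,
                      seed = childSeed(seed, 1L))
    n <- length(g$labels)
    tr <- withSeed(childSeed(seed, 2L),
      unlist(lapply(split(seq_len(n), g$labels), sample,
                    size = trainPerClass)))
    te <- setdiff(seq_len(n), tr)
    x1 <- view1(tv)[tr, ]; x2 <- view2(tv)[tr, ]; y <- viewLabels(tv)[tr]
    xt1 <- view1(tv)[te, ]; xt2 <- view2(tv)[te, ]
    yt <- viewLabels(tv)[te]
    sp <- networkSpec(ncol(x1), hiddenDim = latentDim)
    cfg <- trainConfig("classification", epochs = epochs, seed = seed)
    cfgx <- trainConfig("classification", seed = seed,
                        epochsPerCrossStep = as.integer(
                          c(epochs / 2, epochs / 2, epochs)))
    acc <- function(bundle, xs)
      mean(max.col(predictBundle(bundle, xs),
                   ties.method = "first") - 1L == yt)
    out <- c(seed = seed)
    if ("single1" %in% models)
      out["single1"] <- acc(trainSingle(sp, x1, y, cfg, "view1"), xt1)
    if ("single2" %in% models)
      out["single2"] <- acc(trainSingle(sp, x2, y, cfg, "view2"), xt2)
    if ("concat" %in% models)
      out["concat"] <- acc(trainConcat(list(sp, sp), list(x1, x2), y, cfg,
                                       c("view1", "view2")),
                           list(xt1, xt2))
    if ("cross" %in% models)
      out["cross"] <- acc(trainCross(list(sp, sp), list(x1, x2), y, cfgx,
                                     c("view1", "view2")),
                          list(xt1, xt2))
    out
  })
  as.data.frame(do.call(rbind, rows))
}

#' Survival-signal recovery experiment on synthetic multi-omics data
#'
#' Generates multi-omics survival data with known true risk, runs the
#' stratified four-fold pipeline (PCA features, latent dimension 10)
#' for the requested integration modes and reports the mean test
#' concordance index per mode next to the oracle concordance of the
#' true risk.
#'
#' @param effectShared,effectUnique risk-coefficient magnitudes of the
#'   shared and modality-unique latent factors (see
#'   [syntheticOmicsConfig()])
#' @param seeds integer vector of experiment seeds
#' @param integrations subset of `c("single1", "single2", "concat",
#'   "cross")`
#' @param nSamples samples per run
#' @param epochs survival training epochs
#' @return data.frame with one row per seed: oracle C-index plus the
#'   mean cross-validated test C-index per integration mode
#' @export
survivalRecoveryExperiment <- function(effectShared = 1, effectUnique = 0,
                                       seeds = 1:3,
                                       integrations = c("single1"),
                                       nSamples = 600L, epochs = 100L) {
  rows <- lapply(seeds, function(seed) {
    sim <- simulateOmicsSurvival(syntheticOmicsConfig(
      nSamples = nSamples, featuresPerModality = c(200L, 200L),
      effectShared = effectShared, effectUnique = effectUnique,
      seed = seed))
    out <- c(seed = seed,
             oracle = concordanceIndex(sim$trueRisk,
                                       survTimes(sim$survival),
                                       eventIndicator(sim$survival)))
    cfg <- trainConfig("survival", epochs = epochs, seed = seed)
    for (ig in integrations) {
      omx <- switch(ig, single1 = sim$omics[1], single2 = sim$omics[2],
                    sim$omics)
      cv <- runCrossValidation(
        omx, sim$survival,
        integration = if (ig %in% c("single1", "single2")) "single"
                      else ig,
        featureMethod = "pca", nComponents = 100L, latentDim = 10L,
        config = cfg, seed = seed)
      out[ig] <- mean(foldValues(cv$reports$cindex))
    }
    out
  })
  as.data.frame(do.call(rbind, rows))
}

#' Consensus analysis: paired-latent distance after Concat vs Cross
#'
#' On shared-signal synthetic omics data (two modalities driven by the
#' same latent factors, latent dimension 10 on PCA features), trains
#' the complementary (ConcatAE) and consensus (CrossAE) survival models
#' on one stratified fold and reports the mean Euclidean distance
#' between the paired test-set latent features of the two modalities.
#' Cross-modality reconstruction explicitly drives this distance down.
#'
#' @param seed integer seed
#' @param nSamples samples
#' @param epochs task-training epochs (CrossAE representation phases
#'   get `epochs/2` each)
#' @return named numeric: mean paired distance for `concat` and `cross`
#' @export
consensusDistanceExperiment <- function(seed = 1L, nSamples = 600L,
                                        epochs = 100L) {
  sim <- simulateOmicsSurvival(syntheticOmicsConfig(
    nSamples = nSamples, featuresPerModality = c(200L, 200L),
    effectShared = 1, effectUnique = 0, seed = seed))
  fold <- stratifiedFolds(eventIndicator(sim$survival),
                          seed = seed)[[1]]
  prep <- lapply(sim$omics, function(om)
    preprocessFold(om, fold@trainIdx, fold@valIdx, fold@testIdx,
                   featureMethod = "pca", nComponents = 100L))
  xsTrain <- lapply(prep, function(p) omicsValues(p$train))
  xsTest <- lapply(prep, function(p) omicsValues(p$test))
  specs <- lapply(xsTrain, function(x) networkSpec(ncol(x),
                                                   hiddenDim = 10L))
  survTrain <- sim$survival[fold@trainIdx]
  cfg <- trainConfig("survival", epochs = epochs, seed = seed)
  cfgx <- trainConfig("survival", seed = seed,
                      epochsPerCrossStep = as.integer(
                        c(epochs / 2, epochs / 2, epochs)))
  bc <- trainConcat(specs, xsTrain, survTrain, cfg)
  bx <- trainCross(specs, xsTrain, survTrain, cfgx)
  dist <- function(b) pairedHiddenDistance(
    encodeBundle(b, xsTest)[[1]], encodeBundle(b, xsTest)[[2]])$mean
  c(concat = dist(bc), cross = dist(bx))
}
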