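## Subset an OmicsMatrix to a sample index set (keeps modality tag).
omicsSubset <- function(om, idx) {
  OmicsMatrix(omicsValues(om)[idx, , drop = FALSE], modality = modality(om))
}

## Fit the train-only preprocessing for one modality and apply it to the
## three splits. Returns list(train, val, test, transforms).
preprocessFold <- function(om, trainIdx, valIdx, testIdx,
                           featureMethod = "pca", nComponents = 100L,
                           k = 1000L, log2First = FALSE,
                           minmaxClip = FALSE) {
  if (log2First) om <- log2Transform(om)
  tr <- omicsSubset(om, trainIdx)
  mm <- minmaxFit(tr)
  sets <- list(train = tr, val = omicsSubset(om, valIdx),
               test = omicsSubset(om, testIdx))
  sets <- lapply(sets, function(s) applyTransform(mm, s, clip = minmaxClip))
  transforms <- list(minmax = mm)
  if (featureMethod != "none") {
    ft <- if (featureMethod == "pca") {
      nc <- min(nComponents, length(trainIdx) - 1L, ncol(omicsValues(om)))
      pcaFit(sets$train, nc)
    } else {
      varianceSelectFit(sets$train, min(k, ncol(omicsValues(om))))
    }
    sets <- lapply(sets, function(s) applyTransform(ft, s))
    transforms$features <- ft
  }
  c(sets, list(transforms = transforms))
}

#' Stratified cross-validated training and evaluation
#'
#' Runs the full pipeline per fold: train-only preprocessing (optional
#' log2(X+1) for expression-like modalities, min-max scaling, then PCA
#' or top-variance selection), model training with per-epoch validation
#' tracking, checkpoint selection at the best validation epoch, and
#' test-set evaluation. Stratification uses the class label
#' (classification) or the event indicator (survival).
#'
#' @param omics list of [OmicsMatrix-class] (length 1 for
#'   `integration = "single"`), aligned on samples
#' @param outcome integer class labels in `0..C-1` or a
#'   [SurvivalData-class]
#' @param integration `"single"`, `"concat"` or `"cross"`
#' @param featureMethod `"pca"` (default, 100 components),
#'   `"variance"` (top 1000) or `"none"`
#' @param nComponents,k dimensionality of the two feature methods;
#'   both are capped at what the training split supports
#' @param latentDim latent dimension per modality (default: the
#'   [networkSpec()] one-tenth rule)
#' @param config a [TrainConfig-class]; its seed is re-derived per fold
#' @param log2Modalities modality names to log2(X+1)-transform first
#' @param nFolds,fractions,seed passed to [stratifiedFolds()]
#' @param interleave CrossAE phase interleaving, see [trainCross()]
#' @param keepBundles also return the per-fold trained
#'   [ModelBundle-class] objects and fitted transforms (under `bundles`
#'   and `transforms`), enabling later re-evaluation
#' @return list with `reports` (named list of [MetricsReport-class];
#'   `accuracy`/`weighted_precision`/`weighted_recall` for
#'   classification, `cindex` for survival), `perFold` (data.frame of
#'   per-fold test metrics and selected epochs) and `folds` (the
#'   [FoldAssignment-class] list)
#' @examples
#' \donttest{
#' sim <- simulateOmicsSurvival(syntheticOmicsConfig(nSamples = 120,
#'   featuresPerModality = c(40, 40)))
#' cv <- runCrossValidation(sim$omics, sim$survival,
#'   integration = "concat", featureMethod = "none", latentDim = 5,
#'   config = trainConfig("survival", epochs = 5, batchSize = 32))
#' cv$reports$cindex
#' }
#' @export
runCrossValidation <- function(omics, outcome,
                               integration = c("single", "concat", "cross"),
                               featureMethod = c("pca", "variance", "none"),
                               nComponents = 100L, k = 1000L,
                               latentDim = NULL,
                               config = trainConfig(),
                               log2Modalities = character(),
                               nFolds = 4L,
                               fractions = c(0.60, 0.15, 0.25),
                               seed = 1L, interleave = FALSE,
                               keepBundles = FALSE) {
  integration <- match.arg(integration)
  featureMethod <- match.arg(featureMethod)
  if (nFolds < 2L) stop("'nFolds' must be >= 2")
  if (integration == "single" && length(omics) != 1L)
    stop("single-modality integration takes exactly one OmicsMatrix")
  classification <- config@endpoint == "classification"
  n <- length(sampleIds(omics[[1]]))
  ids <- sampleIds(omics[[1]])
  for (om in omics[-1])
    if (!identical(sampleIds(om), ids))
      stop("sample ids differ across modalities: ", modality(om))
  if (classification) {
    labels <- as.integer(outcome)
    strata <- labels
  } else {
    if (!identical(sampleIds(outcome), ids))
      stop("survival sample ids do not match the omics matrices")
    strata <- eventIndicator(outcome)
  }
  folds <- stratifiedFolds(strata, fractions, nFolds, seed)
  modNames <- vapply(omics, modality, character(1))

  perFold <- list()
  vals <- list()
  bundles <- if (keepBundles) vector("list", nFolds) else NULL
  transforms <- if (keepBundles) vector("list", nFolds) else NULL
  for (f in seq_len(nFolds)) {
    fa <- folds[[f]]
    prep <- lapply(omics, function(om)
      preprocessFold(om, fa@trainIdx, fa@valIdx, fa@testIdx,
                     featureMethod, nComponents, k,
                     log2First = modality(om) %in% log2Modalities))
    xsTrain <- lapply(prep, function(p) omicsValues(p$train))
    xsVal <- lapply(prep, function(p) omicsValues(p$val))
    xsTest <- lapply(prep, function(p) omicsValues(p$test))
    specs <- lapply(xsTrain, function(x)
      if (is.null(latentDim)) networkSpec(ncol(x))
      else networkSpec(ncol(x), hiddenDim = latentDim))
    cfgF <- initialize(config, seed = childSeed(config@seed, f))
    outTrain <- if (classification) labels[fa@trainIdx]
                else outcome[fa@trainIdx]
    outVal <- if (classification) labels[fa@valIdx] else outcome[fa@valIdx]
    bundle <- switch(integration,
      single = trainSingle(specs[[1]], xsTrain[[1]], outTrain, cfgF,
                           modality = modNames[1], valX = xsVal[[1]],
                           valOutcome = outVal),
      concat = trainConcat(specs, xsTrain, outTrain, cfgF,
                           modalities = modNames, valXs = xsVal,
                           valOutcome = outVal),
      cross = trainCross(specs, xsTrain, outTrain, cfgF,
                         modalities = modNames, valXs = xsVal,
                         valOutcome = outVal, interleave = interleave))
    pred <- predictBundle(bundle, xsTest)
    if (classification) {
      predLab <- max.col(pred, ties.method = "first") - 1L
      m <- classificationMetrics(predLab, labels[fa@testIdx])
    } else {
      so <- outcome[fa@testIdx]
      m <- c(cindex = concordanceIndex(pred, survTimes(so),
                                       eventIndicator(so)))
    }
    vals[[f]] <- m
    perFold[[f]] <- data.frame(fold = f, t(m),
      bestEpoch = attr(bundle@trace, "bestEpoch") %||% NA_integer_)
    if (keepBundles) {
      bundles[[f]] <- bundle
      transforms[[f]] <- lapply(prep, `[[`, "transforms")
    }
  }
  metricNames <- names(vals[[1]])
  reports <- lapply(metricNames, function(nm)
    new("MetricsReport", metricName = nm,
        endpoint = config@endpoint,
        foldValues = vapply(vals, `[[`, numeric(1), nm)))
  names(reports) <- metricNames
  out <- list(reports = reports, perFold = do.call(rbind, perFold),
              folds = folds)
  if (keepBundles) {
    out$bundles <- bundles
    out$transforms <- transforms
  }
  out
}
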