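#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata `metadata<-` DataFrame
NULL

## ---------------------------------------------------------------------------
## OmicsMatrix
## ---------------------------------------------------------------------------

#' Single-modality omics matrix
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one continuous omics modality (e.g. gene expression, DNA methylation,
#' miRNA expression, copy-number calls). Features are rows and samples are
#' columns, following Bioconductor convention; `omicsValues()` returns the
#' transposed samples x features matrix used by the model code.
#'
#' @slot modality single character tag naming the modality
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(modality = "character"))

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || is.na(object@modality) ||
      !nzchar(object@modality))
    msg <- c(msg, "'modality' must be a single non-empty string")
  fid <- rownames(object); sid <- colnames(object)
  if (is.null(fid) || anyDuplicated(fid))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, samples in rows and features in columns
#'   (the orientation produced by the generators and expected by the
#'   models; it is transposed internally to the Bioconductor
#'   features x samples layout)
#' @param sampleIds,featureIds character identifiers; default to the
#'   dimnames of `values`, or `S1..Sn` / `F1..Fp` when absent
#' @param modality single character modality tag, e.g. `"GeneExp"`
#' @return an [OmicsMatrix-class] object
#' @examples
#' om <- OmicsMatrix(matrix(rnorm(20), 4, 5), modality = "GeneExp")
#' om
#' @export
OmicsMatrix <- function(values, sampleIds = rownames(values),
                        featureIds = colnames(values),
                        modality = "unnamed") {
  values <- as.matrix(values)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%0*d", nchar(nrow(values)), seq_len(nrow(values)))
  if (is.null(featureIds))
    featureIds <- sprintf("F%d", seq_len(ncol(values)))
  a <- t(values)
  dimnames(a) <- list(featureIds, sampleIds)
  new("OmicsMatrix",
      SummarizedExperiment(assays = list(values = a)),
      modality = modality)
}

#' @rdname accessors
#' @export
setMethod("modality", "OmicsMatrix", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x) t(assay(x, "values")))

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s]: %d samples x %d features\n",
              object@modality, ncol(object), nrow(object)))
})

## ---------------------------------------------------------------------------
## SurvivalData
## ---------------------------------------------------------------------------

#' Right-censored survival outcomes
#'
#' Per-sample survival time (days) and event indicator
#' (1 = event observed, 0 = right-censored).
#'
#' @slot sampleId character sample identifiers (unique)
#' @slot time positive numeric survival/censoring times
#' @slot event integer 0/1 event indicators
#' @export
setClass("SurvivalData",
  representation(sampleId = "character", time = "numeric", event = "integer"))

setValidity("SurvivalData", function(object) {
  msg <- character()
  n <- length(object@sampleId)
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "sampleId, time and event must have equal length")
  if (anyDuplicated(object@sampleId))
    msg <- c(msg, "sample ids must be unique")
  if (any(!is.finite(object@time)) || any(object@time <= 0))
    msg <- c(msg, "all times must be positive and finite")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SurvivalData object
#'
#' @param sampleId character identifiers
#' @param time positive times (days)
#' @param event 0/1 event indicator (1 = event observed)
#' @return a [SurvivalData-class] object
#' @examples
#' SurvivalData(c("a", "b"), c(100, 250), c(1, 0))
#' @export
SurvivalData <- function(sampleId, time, event) {
  new("SurvivalData", sampleId = as.character(sampleId),
      time = as.numeric(time), event = as.integer(event))
}

#' @rdname accessors
#' @export
setMethod("sampleIds", "SurvivalData", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("survTimes", "SurvivalData", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("eventIndicator", "SurvivalData", function(x) x@event)

#' @export
#' @describeIn SurvivalData-class number of samples
setMethod("length", "SurvivalData", function(x) length(x@sampleId))

setMethod("show", "SurvivalData", function(object) {
  cat(sprintf("SurvivalData: %d samples, %d events (%.1f%% censored)\n",
              length(object), sum(object@event),
              100 * mean(object@event == 0L)))
})

#' @export
#' @describeIn SurvivalData-class subset samples
setMethod("[", "SurvivalData", function(x, i, j, ..., drop = TRUE) {
  new("SurvivalData", sampleId = x@sampleId[i], time = x@time[i],
      event = x@event[i])
})

#' @export
#' @describeIn SurvivalData-class coerce to data.frame
as.data.frame.SurvivalData <- function(x, ...) {
  data.frame(sample_id = x@sampleId, time = x@time, event = x@event,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## TwoViewDataset
## ---------------------------------------------------------------------------

#' Paired two-view image dataset
#'
#' Holds two flattened pixel views of the same underlying images: view 1
#' is the (possibly corrupted) original and view 2 the (possibly
#' corrupted) 90-degree counter-clockwise rotation. Pixels are column-major
#' flattened to length `h*w` and lie in \[0, 1\].
#'
#' @slot view1,view2 numeric matrices, n_samples x n_pixels
#' @slot labels integer class label per sample, in `0..C-1`
#' @slot noiseKind one of `"erasing"`, `"gaussian"`, `"none"`
#' @export
setClass("TwoViewDataset",
  representation(view1 = "matrix", view2 = "matrix", labels = "integer",
                 noiseKind = "character"))

setValidity("TwoViewDataset", function(object) {
  msg <- character()
  if (!identical(dim(object@view1), dim(object@view2)))
    msg <- c(msg, "view1 and view2 must have identical dimensions")
  if (nrow(object@view1) != length(object@labels))
    msg <- c(msg, "one label per sample required")
  rng <- range(object@view1, object@view2)
  if (rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "all pixel values must lie in [0, 1]")
  if (length(object@labels) && min(object@labels) < 0L)
    msg <- c(msg, "labels must be non-negative integers")
  if (!object@noiseKind %in% c("erasing", "gaussian", "none"))
    msg <- c(msg, "noiseKind must be 'erasing', 'gaussian' or 'none'")
  if (length(msg)) msg else TRUE
})

#' @param x a TwoViewDataset
#' @describeIn TwoViewDataset-class view-1 pixel matrix
#' @export
view1 <- function(x) x@view1

#' @describeIn TwoViewDataset-class view-2 pixel matrix
#' @export
view2 <- function(x) x@view2

#' @describeIn TwoViewDataset-class integer class labels (0-based)
#' @export
viewLabels <- function(x) x@labels

setMethod("show", "TwoViewDataset", function(object) {
  cat(sprintf(
    "TwoViewDataset: %d samples, %d pixels/view, %d classes, noise = %s\n",
    nrow(object@view1), ncol(object@view1),
    length(unique(object@labels)), object@noiseKind))
})

## ---------------------------------------------------------------------------
## HiddenFeatures
## ---------------------------------------------------------------------------

#' Latent (hidden) features produced by an encoder
#'
#' @slot z numeric matrix, n_samples x latent_dim
#' @slot modality character tag of the encoding modality
#' @export
setClass("HiddenFeatures",
  representation(z = "matrix", modality = "character"))

setValidity("HiddenFeatures", function(object) {
  if (any(!is.finite(object@z))) "latent values must be finite" else TRUE
})

#' Construct a HiddenFeatures object
#' @param z samples x latent-dim numeric matrix
#' @param modality modality tag
#' @return a [HiddenFeatures-class] object
#' @export
HiddenFeatures <- function(z, modality = "unnamed") {
  new("HiddenFeatures", z = as.matrix(z), modality = modality)
}

#' @rdname accessors
#' @export
setMethod("latentMatrix", "HiddenFeatures", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("modality", "HiddenFeatures", function(x) x@modality)

setMethod("show", "HiddenFeatures", function(object) {
  cat(sprintf("HiddenFeatures [%s]: %d samples x %d dims\n",
              object@modality, nrow(object@z), ncol(object@z)))
})

## ---------------------------------------------------------------------------
## FittedTransform / FoldAssignment
## ---------------------------------------------------------------------------

#' A preprocessing transform fitted on training rows only
#'
#' `kind` is one of `"minmax"` (per-feature min/max scaling to \[0, 1\]),
#' `"variance_select"` (top-k features by training variance) or `"pca"`
#' (training-mean centering plus projection on leading principal
#' components). Apply with [applyTransform()].
#'
#' @slot kind character transform kind
#' @slot params list of fitted parameters (see [applyTransform()])
#' @slot featureIds character feature ids of the input space
#' @export
setClass("FittedTransform",
  representation(kind = "character", params = "list",
                 featureIds = "character"))

setValidity("FittedTransform", function(object) {
  if (!object@kind %in% c("minmax", "variance_select", "pca"))
    "kind must be 'minmax', 'variance_select' or 'pca'" else TRUE
})

setMethod("show", "FittedTransform", function(object) {
  cat(sprintf("FittedTransform[%s] on %d input features\n",
              object@kind, length(object@featureIds)))
})

#' One fold of a stratified train/validation/test split
#'
#' @slot foldIndex integer fold number (1-based)
#' @slot trainIdx,valIdx,testIdx disjoint sample index sets covering all
#'   samples
#' @export
setClass("FoldAssignment",
  representation(foldIndex = "integer", trainIdx = "integer",
                 valIdx = "integer", testIdx = "integer"))

setValidity("FoldAssignment", function(object) {
  all3 <- c(object@trainIdx, object@valIdx, object@testIdx)
  if (anyDuplicated(all3))
    return("train/val/test index sets must be pairwise disjoint")
  if (!setequal(all3, seq_len(length(all3))))
    return("train/val/test must cover samples 1..n exactly once")
  TRUE
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment %d: train %d / val %d / test %d\n",
              object@foldIndex, length(object@trainIdx),
              length(object@valIdx), length(object@testIdx)))
})

## ---------------------------------------------------------------------------
## NetworkSpec / ModelBundle / TrainConfig / MetricsReport
## ---------------------------------------------------------------------------

#' Architecture of one autoencoder (plus optional task head)
#'
#' See [networkSpec()] for construction and defaults.
#'
#' @slot inputDim,hiddenDim integer input and latent dimensions
#' @slot encoderWidths,decoderWidths integer widths of intermediate
#'   fully connected layers (may be empty for a single linear layer)
#' @slot activation activation of intermediate layers, `"relu"` or
#'   `"linear"`
#' @slot decoderOutputActivation `"sigmoid"` (for \[0,1\]-scaled inputs)
#'   or `"linear"`
#' @export
setClass("NetworkSpec",
  representation(inputDim = "integer", hiddenDim = "integer",
                 encoderWidths = "integer", decoderWidths = "integer",
                 activation = "character",
                 decoderOutputActivation = "character"))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (object@inputDim < 1L || object@hiddenDim < 1L)
    msg <- c(msg, "inputDim and hiddenDim must be positive")
  if (!object@activation %in% c("relu", "linear"))
    msg <- c(msg, "activation must be 'relu' or 'linear'")
  if (!object@decoderOutputActivation %in% c("sigmoid", "linear"))
    msg <- c(msg, "decoderOutputActivation must be 'sigmoid' or 'linear'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: %d -> [%s] -> %d (activation %s)\n",
              object@inputDim,
              paste(object@encoderWidths, collapse = ","),
              object@hiddenDim, object@activation))
})

#' A trained integration model
#'
#' Holds one (encoder, decoder) parameter pair per modality plus one
#' shared task head, together with the per-epoch loss trace recorded
#' during training. Construct via [trainSingle()], [trainConcat()] or
#' [trainCross()].
#'
#' @slot specs list of [NetworkSpec-class], one per modality
#' @slot params list: `modalities` (per-modality `encoder`/`decoder`
#'   layer parameters) and `head`
#' @slot integration `"single"`, `"concat"` or `"cross"`
#' @slot endpoint `"classification"` or `"survival"`
#' @slot modalities character modality names (configured order)
#' @slot nClasses integer number of classes (classification only)
#' @slot trace data.frame of per-epoch losses/metrics
#' @export
setClass("ModelBundle",
  representation(specs = "list", params = "list", integration = "character",
                 endpoint = "character", modalities = "character",
                 nClasses = "integer", trace = "data.frame"))

setValidity("ModelBundle", function(object) {
  msg <- character()
  if (!object@integration %in% c("single", "concat", "cross"))
    msg <- c(msg, "integration must be 'single', 'concat' or 'cross'")
  if (!object@endpoint %in% c("classification", "survival"))
    msg <- c(msg, "endpoint must be 'classification' or 'survival'")
  if (length(object@specs) != length(object@modalities))
    msg <- c(msg, "one NetworkSpec per modality required")
  hd <- vapply(object@specs, function(s) s@hiddenDim, integer(1))
  if (object@integration == "cross" && length(unique(hd)) > 1L)
    msg <- c(msg, "cross integration requires equal latent dims")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle [%s, %s]: modalities %s; latent dims %s\n",
              object@integration, object@endpoint,
              paste(object@modalities, collapse = "+"),
              paste(vapply(object@specs, function(s) s@hiddenDim,
                           integer(1)), collapse = ",")))
})

#' Training configuration
#'
#' See [trainConfig()] for construction and the defaults
#' (classification: batch size 32; survival: batch size 128; Adam with
#' learning rate 0.001 and 200 epochs).
#'
#' @slot batchSize,epochs positive integers
#' @slot learningRate positive numeric
#' @slot seed integer RNG seed controlling init and batch order
#' @slot optimizer `"adam"`
#' @slot endpoint `"classification"` or `"survival"`
#' @slot epochsPerCrossStep integer triple of epochs for the three
#'   CrossAE phases (per-modality reconstruction, cross-modality
#'   reconstruction, task training)
#' @export
setClass("TrainConfig",
  representation(batchSize = "integer", learningRate = "numeric",
                 epochs = "integer", seed = "integer",
                 optimizer = "character", endpoint = "character",
                 epochsPerCrossStep = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (!object@optimizer %in% "adam") msg <- c(msg, "optimizer must be 'adam'")
  if (!object@endpoint %in% c("classification", "survival"))
    msg <- c(msg, "endpoint must be 'classification' or 'survival'")
  if (length(object@epochsPerCrossStep) != 3L ||
      any(object@epochsPerCrossStep < 0L))
    msg <- c(msg, "epochsPerCrossStep must be three non-negative integers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig [%s]: batch %d, lr %g, epochs %d, seed %d, cross steps %s\n",
    object@endpoint, object@batchSize, object@learningRate, object@epochs,
    object@seed, paste(object@epochsPerCrossStep, collapse = "/")))
})

#' Cross-validated metric report
#'
#' Per-fold test metric values with their mean and standard deviation,
#' shown in the `mean ± sd` reporting style.
#'
#' @slot metricName e.g. `"accuracy"` or `"cindex"`
#' @slot endpoint `"classification"` or `"survival"`
#' @slot foldValues numeric per-fold test values
#' @export
setClass("MetricsReport",
  representation(metricName = "character", endpoint = "character",
                 foldValues = "numeric"))

setValidity("MetricsReport", function(object) {
  if (length(object@foldValues) < 1L) "at least one fold value required"
  else TRUE
})

#' @rdname accessors
#' @export
setMethod("foldValues", "MetricsReport", function(x) x@foldValues)

#' Format a metrics report as `mean ± sd`
#'
#' @param report a [MetricsReport-class]
#' @param digits decimal places (default 3)
#' @return character scalar such as `"0.641 ± 0.031"`
#' @export
formatMetricsReport <- function(report, digits = 3) {
  v <- report@foldValues
  s <- if (length(v) > 1L) sd(v) else 0
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean(v), s)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s, %s folds]: %s\n", object@metricName,
              length(object@foldValues), formatMetricsReport(object)))
})
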