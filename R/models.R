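#' Construct a network architecture specification
#'
#' The default architecture is the smallest one consistent with an
#' autoencoder on \[0, 1\]-scaled data: encoder = one hidden fully
#' connected ReLU layer whose width is the rounded geometric mean of
#' input and latent dimension, then a linear map to the latent `z`;
#' the decoder mirrors it and ends in a sigmoid. The default latent
#' size follows the one-tenth rule used for omics inputs (latent 10
#' for 100 PCA components, latent 100 for 1000 top-variance features).
#'
#' @param inputDim number of input features
#' @param hiddenDim latent dimension (default `max(2, round(inputDim/10))`)
#' @param encoderWidths integer widths of intermediate encoder layers;
#'   `integer(0)` gives a single linear layer input -> latent
#' @param decoderWidths intermediate decoder widths (default mirrors the
#'   encoder)
#' @param activation `"relu"` (default) or `"linear"` for intermediate
#'   layers
#' @param decoderOutputActivation `"sigmoid"` (default, for
#'   \[0, 1\]-scaled inputs) or `"linear"`
#' @return a [NetworkSpec-class]
#' @examples
#' networkSpec(100)            # latent 10, hidden width 32
#' networkSpec(1000)           # latent 100
#' @export
networkSpec <- function(inputDim,
                        hiddenDim = max(2L, as.integer(round(inputDim / 10))),
                        encoderWidths = as.integer(
                          round(sqrt(inputDim * hiddenDim))),
                        decoderWidths = rev(encoderWidths),
                        activation = "relu",
                        decoderOutputActivation = "sigmoid") {
  new("NetworkSpec", inputDim = as.integer(inputDim),
      hiddenDim = as.integer(hiddenDim),
      encoderWidths = as.integer(encoderWidths),
      decoderWidths = as.integer(decoderWidths),
      activation = activation,
      decoderOutputActivation = decoderOutputActivation)
}

encoderLayout <- function(spec) {
  widths <- c(spec@inputDim, spec@encoderWidths, spec@hiddenDim)
  acts <- c(rep(spec@activation, length(spec@encoderWidths)), "linear")
  list(widths = widths, acts = acts)
}

decoderLayout <- function(spec) {
  widths <- c(spec@hiddenDim, spec@decoderWidths, spec@inputDim)
  acts <- c(rep(spec@activation, length(spec@decoderWidths)),
            spec@decoderOutputActivation)
  list(widths = widths, acts = acts)
}

#' Initialize autoencoder or head parameters
#'
#' Weights use a uniform fan-in scheme (`U(-1/sqrt(fan_in),
#' 1/sqrt(fan_in))`), drawn from the current RNG stream (or `seed` when
#' given). The classifier head is a single linear layer to `nClasses`
#' logits; the survival head is a two-layer network (hidden width 32,
#' ReLU) to a scalar log-relative hazard.
#'
#' @param spec a [NetworkSpec-class]
#' @param seed optional integer seed
#' @param latentDim head input dimension (sum of latent dims for concat
#'   integration, the common latent dim otherwise)
#' @param endpoint `"classification"` or `"survival"`
#' @param nClasses number of classes (classification only)
#' @param hiddenWidth hidden width of the survival head
#' @return `initAutoencoderParams()`: list with elements `encoder` and
#'   `decoder`; `initHeadParams()`: a single net parameter list
#' @name initParams
#' @export
initAutoencoderParams <- function(spec, seed = NULL) {
  withSeed(seed, {
    e <- encoderLayout(spec); d <- decoderLayout(spec)
    list(encoder = mlpInit(e$widths, e$acts),
         decoder = mlpInit(d$widths, d$acts))
  })
}

#' @rdname initParams
#' @export
initHeadParams <- function(latentDim, endpoint, nClasses = 0L,
                           hiddenWidth = 32L, seed = NULL) {
  withSeed(seed, {
    if (endpoint == "classification") {
      if (nClasses < 2L) stop("classification head needs >= 2 classes")
      mlpInit(c(latentDim, nClasses), "linear")
    } else {
      mlpInit(c(latentDim, hiddenWidth, 1L), c("relu", "linear"))
    }
  })
}

#' Deterministic forward maps of the autoencoder and task heads
#'
#' `aeEncode()` maps inputs to latent features, `aeDecode()` latent
#' features back to the input space, `headClassify()` latent features
#' to class logits, and `headHazard()` latent features to a scalar
#' log-relative hazard per sample.
#'
#' @param spec a [NetworkSpec-class]
#' @param params the matching parameter list from
#'   [initAutoencoderParams()]
#' @param x samples x inputDim matrix
#' @param z samples x latent-dim matrix or [HiddenFeatures-class]
#' @param head a head parameter list from [initHeadParams()]
#' @param modality modality tag attached to the returned latent features
#' @return `aeEncode()`: a [HiddenFeatures-class]; `aeDecode()`: a
#'   reconstruction matrix; `headClassify()`: an n x C logit matrix;
#'   `headHazard()`: a numeric vector of hazards
#' @name forwardOps
#' @export
aeEncode <- function(spec, params, x, modality = "unnamed") {
  x <- as.matrix(x)
  if (ncol(x) != spec@inputDim)
    stop("input has ", ncol(x), " features; spec expects ", spec@inputDim)
  HiddenFeatures(mlpForward(params$encoder, x), modality = modality)
}

#' @rdname forwardOps
#' @export
aeDecode <- function(spec, params, z) {
  z <- if (is(z, "HiddenFeatures")) latentMatrix(z) else as.matrix(z)
  if (ncol(z) != spec@hiddenDim)
    stop("latent has ", ncol(z), " dims; spec expects ", spec@hiddenDim)
  mlpForward(params$decoder, z)
}

#' @rdname forwardOps
#' @export
headClassify <- function(head, z) {
  z <- if (is(z, "HiddenFeatures")) latentMatrix(z) else as.matrix(z)
  if (ncol(z) != nrow(head$W[[1]]))
    stop("latent dimension does not match the head input dimension")
  mlpForward(head, z)
}

#' @rdname forwardOps
#' @export
headHazard <- function(head, z) {
  as.vector(headClassify(head, z))
}

#' Fuse per-modality latent features
#'
#' `fuseConcat()` concatenates latent vectors in the configured
#' modality order (complementary integration: the fused length is the
#' sum of the input lengths). `fuseAverage()` element-wise averages
#' latent vectors of equal dimension (consensus integration).
#'
#' @param zs list of [HiddenFeatures-class] (or matrices), aligned on
#'   samples
#' @return a [HiddenFeatures-class] with the fused latent matrix
#' @name fuseOps
#' @examples
#' z1 <- HiddenFeatures(matrix(c(1, 2), 1), "m1")
#' z2 <- HiddenFeatures(matrix(3, 1), "m2")
#' latentMatrix(fuseConcat(list(z1, z2)))
#' @export
fuseConcat <- function(zs) {
  mats <- lapply(zs, function(z)
    if (is(z, "HiddenFeatures")) latentMatrix(z) else as.matrix(z))
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) > 1L)
    stop("sample counts differ across modalities: ",
         paste(ns, collapse = ", "))
  tags <- vapply(zs, function(z)
    if (is(z, "HiddenFeatures")) modality(z) else "?", character(1))
  HiddenFeatures(do.call(cbind, mats), modality = paste(tags,
                                                        collapse = "+"))
}

#' @rdname fuseOps
#' @export
fuseAverage <- function(zs) {
  mats <- lapply(zs, function(z)
    if (is(z, "HiddenFeatures")) latentMatrix(z) else as.matrix(z))
  dims <- vapply(mats, ncol, integer(1))
  if (length(unique(dims)) > 1L)
    stop("latent dimensions differ across modalities: ",
         paste(dims, collapse = ", "))
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) > 1L)
    stop("sample counts differ across modalities")
  tags <- vapply(zs, function(z)
    if (is(z, "HiddenFeatures")) modality(z) else "?", character(1))
  HiddenFeatures(Reduce(`+`, mats) / length(mats),
                 modality = paste(tags, collapse = "~"))
}

#' Count trainable parameters
#'
#' @param params a net parameter list, an autoencoder pair from
#'   [initAutoencoderParams()], or a [ModelBundle-class]
#' @return total number of scalar weights and biases
#' @export
countParams <- function(params) {
  if (is(params, "ModelBundle")) {
    return(sum(vapply(params@params$modalities, countParams, numeric(1))) +
           countParams(params@params$head))
  }
  if (!is.null(params$W))
    return(sum(vapply(params$W, length, numeric(1))) +
           sum(vapply(params$b, length, numeric(1))))
  sum(vapply(params, countParams, numeric(1)))
}

## ---------------------------------------------------------------------------
## Bundle-level forward helpers
## ---------------------------------------------------------------------------

#' Encode data with a trained bundle and predict with its head
#'
#' `encodeBundle()` returns the per-modality latent features;
#' `fusedLatent()` the integration-specific fused latent matrix
#' (the single modality's latents, their concatenation, or their
#' element-wise average); `predictBundle()` the head output (class
#' logits or hazards).
#'
#' @param bundle a trained [ModelBundle-class]
#' @param xs list of samples x features matrices, one per modality, in
#'   the bundle's modality order (a single matrix is accepted for
#'   single-modality bundles)
#' @return see Description
#' @name bundlePredict
#' @export
encodeBundle <- function(bundle, xs) {
  if (is.matrix(xs)) xs <- list(xs)
  if (length(xs) != length(bundle@modalities))
    stop("expected ", length(bundle@modalities), " modality matrices")
  lapply(seq_along(xs), function(m)
    aeEncode(bundle@specs[[m]], bundle@params$modalities[[m]], xs[[m]],
             modality = bundle@modalities[m]))
}

#' @rdname bundlePredict
#' @export
fusedLatent <- function(bundle, xs) {
  zs <- encodeBundle(bundle, xs)
  switch(bundle@integration,
    single = zs[[1]],
    concat = fuseConcat(zs),
    cross = fuseAverage(zs))
}

#' @rdname bundlePredict
#' @export
predictBundle <- function(bundle, xs) {
  z <- fusedLatent(bundle, xs)
  if (bundle@endpoint == "classification")
    headClassify(bundle@params$head, z)
  else
    headHazard(bundle@params$head, z)
}
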