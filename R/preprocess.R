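#' Remove features containing missing values
#'
#' Column-wise quality control: every feature with at least one missing
#' entry is dropped; the sample set is never touched.
#'
#' @param m an [OmicsMatrix-class]
#' @return an [OmicsMatrix-class] with the offending features removed
#' @export
dropMissingFeatures <- function(m) {
  v <- omicsValues(m)
  keep <- colSums(is.na(v)) == 0L
  if (!any(keep)) stop("all features contain missing values")
  OmicsMatrix(v[, keep, drop = FALSE], modality = modality(m))
}

#' log2(X + 1) transform for expression-like modalities
#'
#' Intended for non-negative abundance measures (FPKM gene expression,
#' RPM miRNA expression); refuses negative input since the transform is
#' reserved for expression-type modalities.
#'
#' @param m an [OmicsMatrix-class] with non-negative values
#' @return the transformed [OmicsMatrix-class]
#' @export
log2Transform <- function(m) {
  v <- omicsValues(m)
  if (any(v < 0, na.rm = TRUE))
    stop("log2(X + 1) requires non-negative values ",
         "(expression-like modalities only)")
  OmicsMatrix(log2(v + 1), modality = modality(m))
}

#' Fit preprocessing transforms on training rows only
#'
#' `minmaxFit()` records per-feature training min/max for scaling to
#' \[0, 1\] (constant training features map to 0). `varianceSelectFit()`
#' records the indices of the `k` features with largest training
#' variance (ties broken by lower feature index). `pcaFit()` records
#' the training mean and the leading principal-component loadings,
#' ordered by decreasing explained variance, with each component's
#' largest-magnitude loading made positive for reproducibility.
#' All three are applied to new data with [applyTransform()] and never
#' see validation or test rows.
#'
#' @param train an [OmicsMatrix-class] of training samples
#' @param k number of features to keep (default 1000)
#' @param nComponents number of principal components (default 100); must
#'   not exceed `min(n_train - 1, n_features)`
#' @return a [FittedTransform-class]
#' @name fitTransforms
#' @examples
#' om <- OmicsMatrix(matrix(rnorm(200), 20, 10), modality = "GeneExp")
#' tf <- minmaxFit(om)
#' range(omicsValues(applyTransform(tf, om)))
NULL

#' @rdname fitTransforms
#' @export
minmaxFit <- function(train) {
  v <- omicsValues(train)
  new("FittedTransform", kind = "minmax",
      params = list(lo = apply(v, 2, min), hi = apply(v, 2, max)),
      featureIds = featureIds(train))
}

#' @rdname fitTransforms
#' @export
varianceSelectFit <- function(train, k = 1000L) {
  if (k <= 0L) stop("'k' must be positive")
  v <- omicsValues(train)
  if (k > ncol(v)) stop("'k' exceeds the number of features")
  vars <- apply(v, 2, var)
  ranked <- order(-vars, seq_along(vars), method = "radix")
  sel <- sort(ranked[seq_len(k)])  # keep original feature order
  new("FittedTransform", kind = "variance_select",
      params = list(indices = sel, variances = vars),
      featureIds = featureIds(train))
}

#' @rdname fitTransforms
#' @export
pcaFit <- function(train, nComponents = 100L) {
  v <- omicsValues(train)
  bound <- min(nrow(v) - 1L, ncol(v))
  if (nComponents < 1L || nComponents > bound)
    stop("'nComponents' must lie in 1..min(n_samples - 1, n_features) = ",
         bound)
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  ## sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  new("FittedTransform", kind = "pca",
      params = list(center = pc$center, rotation = rot,
                    explainedVarianceRatio = evr[seq_len(nComponents)]),
      featureIds = featureIds(train))
}

#' Apply a fitted transform to a matrix in the same feature space
#'
#' @param transform a [FittedTransform-class]
#' @param m an [OmicsMatrix-class] whose features match the transform's
#'   training feature space
#' @param clip for min-max only: clip transformed values into \[0, 1\]
#'   (default `FALSE`; out-of-range test values are kept so no
#'   information is discarded)
#' @return the transformed [OmicsMatrix-class]
#' @export
applyTransform <- function(transform, m, clip = FALSE) {
  if (!identical(featureIds(m), transform@featureIds))
    stop("feature ids of 'm' do not match the transform's feature space")
  v <- omicsValues(m)
  p <- transform@params
  out <- switch(transform@kind,
    minmax = {
      span <- p$hi - p$lo
      const <- span == 0
      span[const] <- 1
      r <- sweep(sweep(v, 2, p$lo, "-"), 2, span, "/")
      r[, const] <- 0
      if (clip) r <- clip01(r)
      r
    },
    variance_select = v[, p$indices, drop = FALSE],
    pca = {
      r <- sweep(v, 2, p$center, "-") %*% p$rotation
      colnames(r) <- colnames(p$rotation)
      r
    })
  OmicsMatrix(out, modality = modality(m))
}

#' Serialize a fitted transform to a JSON sidecar file
#'
#' The file stores `kind`, the input feature ids and the fitted
#' parameters (vectors, and matrices as nested row arrays), so a fold's
#' preprocessing can be re-applied bit-identically in a later session.
#'
#' @param transform a [FittedTransform-class]
#' @param path file path (`.json`)
#' @return `writeTransform()` returns `path` invisibly;
#'   `readTransform()` the reconstructed [FittedTransform-class]
#' @name transformIO
#' @export
writeTransform <- function(transform, path) {
  obj <- list(kind = transform@kind, featureIds = transform@featureIds,
              params = transform@params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transformIO
#' @export
readTransform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  if (obj$kind == "minmax") {
    p$lo <- stats::setNames(as.numeric(p$lo), obj$featureIds)
    p$hi <- stats::setNames(as.numeric(p$hi), obj$featureIds)
  } else if (obj$kind == "variance_select") {
    p$indices <- as.integer(p$indices)
  } else if (obj$kind == "pca") {
    p$center <- stats::setNames(as.numeric(p$center), obj$featureIds)
    p$rotation <- as.matrix(p$rotation)
    rownames(p$rotation) <- obj$featureIds
    colnames(p$rotation) <- paste0("PC", seq_len(ncol(p$rotation)))
  }
  new("FittedTransform", kind = obj$kind, params = p,
      featureIds = as.character(obj$featureIds))
}

#' Stratified four-fold 60/15/25 splitting
#'
#' Partitions the samples into `nFolds` stratified test sets (~25% each
#' under the default fractions); within each fold the remaining samples
#' are split stratified into training (~60% of total) and validation
#' (~15% of total). Stratum proportions are preserved within +/- 1
#' sample per stratum per set, and the union of test sets across folds
#' is exactly the full sample set.
#'
#' @param strataLabels one stratum label per sample (class label for
#'   classification; event indicator for survival)
#' @param fractions train/validation/test fractions, summing to 1
#' @param nFolds number of folds (default 4)
#' @param seed integer seed; the split is a pure function of it
#' @return list of `nFolds` [FoldAssignment-class] objects
#' @examples
#' folds <- stratifiedFolds(rep(0:1, each = 50), seed = 1)
#' folds[[1]]
#' @export
stratifiedFolds <- function(strataLabels, fractions = c(0.60, 0.15, 0.25),
                            nFolds = 4L, seed = 1L) {
  n <- length(strataLabels)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("'fractions' must be three values summing to 1")
  strata <- split(seq_len(n), strataLabels)
  small <- lengths(strata) < nFolds
  if (any(small))
    stop("stratum '", names(strata)[small][1], "' has fewer samples (",
         lengths(strata)[small][1], ") than nFolds = ", nFolds)
  trFrac <- fractions[1] / (fractions[1] + fractions[2])
  withSeed(seed, {
    testSets <- vector("list", nFolds)
    sizes <- integer(nFolds)
    for (j in seq_along(strata)) {
      sp <- sample(strata[[j]])
      len <- length(sp)
      counts <- rep(len %/% nFolds, nFolds)
      rem <- len %% nFolds
      if (rem > 0) {
        ## hand leftovers to the currently smallest test sets so the
        ## fold sizes stay balanced across strata
        extra <- order(sizes, seq_len(nFolds))[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      pos <- 1L
      for (f in seq_len(nFolds)) {
        if (counts[f] > 0L) {
          testSets[[f]] <- c(testSets[[f]], sp[pos:(pos + counts[f] - 1L)])
          pos <- pos + counts[f]
        }
      }
      sizes <- sizes + counts
    }
    lapply(seq_len(nFolds), function(f) {
      test <- sort(testSets[[f]])
      rest <- setdiff(seq_len(n), test)
      restStrata <- split(rest, strataLabels[rest])
      tr <- integer(0); va <- integer(0)
      for (rs in restStrata) {
        rsp <- sample(rs)
        k <- round(trFrac * length(rsp))
        tr <- c(tr, rsp[seq_len(k)])
        va <- c(va, if (k < length(rsp)) rsp[(k + 1L):length(rsp)]
                else integer(0))
      }
      new("FoldAssignment", foldIndex = as.integer(f),
          trainIdx = sort(tr), valIdx = sort(va), testIdx = test)
    })
  })
}
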