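#' Classification metrics: accuracy, weighted precision, weighted recall
#'
#' Weighted precision/recall are class-support-weighted averages of the
#' per-class precision/recall; a class never predicted contributes
#' precision 0 with its true support weight.
#'
#' @param predicted,truth equal-length label vectors (any atomic type)
#' @return named numeric vector `c(accuracy, weighted_precision,
#'   weighted_recall)`
#' @examples
#' classificationMetrics(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
#' @export
classificationMetrics <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop("'predicted' and 'truth' must be non-empty and of equal length")
  lev <- sort(unique(c(predicted, truth)))
  pf <- factor(predicted, levels = lev)
  tf <- factor(truth, levels = lev)
  cm <- table(truth = tf, predicted = pf)
  support <- rowSums(cm)
  predTot <- colSums(cm)
  tp <- diag(cm)
  prec <- ifelse(predTot > 0, tp / predTot, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  w <- support / sum(support)
  c(accuracy = sum(tp) / length(truth),
    weighted_precision = sum(w * prec),
    weighted_recall = sum(w * rec))
}

#' Harrell's concordance index for right-censored survival
#'
#' Over all ordered pairs `(i, j)` with `T_i < T_j` and `event_i = 1`
#' (the comparable pairs), counts 1 when `h_i > h_j`, 0.5 when
#' `h_i == h_j`, and returns the concordant fraction. 0.5 is chance
#' level; 1 is a perfectly anti-ordered hazard.
#'
#' @param h per-sample hazard scores (higher = shorter expected
#'   survival)
#' @param time survival/censoring times
#' @param event 0/1 event indicators
#' @return concordance index in \[0, 1\]
#' @examples
#' concordanceIndex(c(3, 1, 0, 2), c(2, 4, 6, 8), c(1, 0, 1, 0))
#' @export
concordanceIndex <- function(h, time, event) {
  h <- as.numeric(h); time <- as.numeric(time); event <- as.integer(event)
  n <- length(h)
  if (length(time) != n || length(event) != n)
    stop("'h', 'time' and 'event' must have equal length")
  conc <- 0; comp <- 0
  ## vectorized over the event samples: pair (i, j) comparable iff
  ## T_i < T_j and event_i = 1
  for (i in which(event == 1L)) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0L) next
    comp <- comp + m
    conc <- conc + sum(h[i] > h[later]) + 0.5 * sum(h[i] == h[later])
  }
  if (comp == 0)
    stop("no comparable pairs: concordance index undefined")
  conc / comp
}

#' Per-sample Euclidean distance between paired latent features
#'
#' The consensus analysis of integration models: the Euclidean norm of
#' `z_a - z_b` per sample, with the summary statistics needed for
#' violin/bar-style reporting.
#'
#' @param za,zb [HiddenFeatures-class] (or matrices) of equal dimensions,
#'   aligned on samples
#' @return list with `distances` (numeric per sample), `mean`, and
#'   `quartiles` (25/50/75%)
#' @examples
#' pairedHiddenDistance(matrix(0, 1, 2), matrix(c(3, 4), 1, 2))$mean
#' @export
pairedHiddenDistance <- function(za, zb) {
  a <- if (is(za, "HiddenFeatures")) latentMatrix(za) else as.matrix(za)
  b <- if (is(zb, "HiddenFeatures")) latentMatrix(zb) else as.matrix(zb)
  if (!identical(dim(a), dim(b)))
    stop("'za' and 'zb' must have identical dimensions")
  d <- sqrt(rowSums((a - b)^2))
  list(distances = d, mean = mean(d),
       quartiles = quantile(d, c(0.25, 0.5, 0.75)))
}

#' Tidy per-sample latent-distance table for a trained bundle
#'
#' Encodes the supplied data with each modality's encoder and reports
#' the per-sample Euclidean distance for every modality pair — the
#' consensus analysis comparing integration methods.
#'
#' @param bundle a trained [ModelBundle-class] with >= 2 modalities
#' @param xs list of samples x features matrices, one per modality
#' @return data.frame with columns `pair`, `sample`, `distance`,
#'   `integration`
#' @export
pairedDistanceReport <- function(bundle, xs) {
  zs <- encodeBundle(bundle, xs)
  if (length(zs) < 2L)
    stop("latent-distance analysis needs >= 2 modalities")
  out <- list()
  for (a in seq_along(zs)) for (b in seq_along(zs)) if (a < b) {
    d <- pairedHiddenDistance(zs[[a]], zs[[b]])
    out[[length(out) + 1L]] <- data.frame(
      pair = paste(modality(zs[[a]]), modality(zs[[b]]), sep = "+"),
      sample = seq_along(d$distances), distance = d$distances,
      integration = bundle@integration)
  }
  do.call(rbind, out)
}
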