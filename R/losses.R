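#' Reconstruction, classification and survival losses
#'
#' `mseRecon()` is the mean squared error over all entries (batch x
#' features), so losses are comparable across modalities of different
#' widths. `multiReconLoss()` sums the per-modality mean squared errors
#' (the joint reconstruction loss of complementary integration).
#' `crossReconLoss()` sums the two cross-reconstruction errors, where
#' `xhat12` reconstructs modality 1 from modality 2's latent features
#' and `xhat21` reconstructs modality 2 from modality 1's.
#' `crossEntropyLoss()` is the softmax negative log-likelihood averaged
#' over the batch. `coxNLL()` is the Cox negative log partial
#' likelihood under the Breslow convention.
#'
#' @param x,xhat matrices of equal shape (input and reconstruction)
#' @param xs,xhats lists of per-modality inputs and reconstructions
#' @param x1,x2,xhat12,xhat21 the two modality inputs and their
#'   cross-reconstructions
#' @param logits n x C matrix of unnormalized class scores
#' @param labels integer class labels in `0..C-1`
#' @param h numeric vector of per-sample log-relative hazards
#' @param time positive survival/censoring times
#' @param event 0/1 event indicators (1 = event observed)
#' @return scalar loss value
#' @name losses
NULL

#' @rdname losses
#' @export
mseRecon <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!identical(dim(x), dim(xhat)))
    stop("'x' and 'xhat' must have the same shape")
  mean((x - xhat)^2)
}

#' @rdname losses
#' @export
multiReconLoss <- function(xs, xhats) {
  if (length(xs) != length(xhats))
    stop("one reconstruction per modality required")
  sum(mapply(mseRecon, xs, xhats))
}

#' @rdname losses
#' @export
crossReconLoss <- function(x1, x2, xhat12, xhat21) {
  mseRecon(x1, xhat12) + mseRecon(x2, xhat21)
}

#' @rdname losses
#' @export
crossEntropyLoss <- function(logits, labels) {
  logits <- as.matrix(logits)
  labels <- as.integer(labels)
  C <- ncol(logits)
  if (any(labels < 0L) || any(labels >= C))
    stop("labels must lie in 0..C-1")
  n <- nrow(logits)
  m <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(seq_len(n), labels + 1L)]
  mean(lse - picked)
}

#' @rdname losses
#' @details
#' The Cox loss is `-(1/N_ob) * sum_{i: event_i = 1} (h_i - log
#' sum_{j: T_j >= T_i} exp(h_j))` with `N_ob` the number of events; the
#' risk set of an event includes every sample (censored or not) with
#' `T_j >= T_i`, so tied event times share the full tied risk set
#' (Breslow convention). It is invariant to adding a constant to all
#' hazards and to reordering samples. A batch with no events has no
#' defined loss and raises an error (training skips such batches).
#' @export
coxNLL <- function(h, time, event) {
  h <- as.numeric(h); time <- as.numeric(time); event <- as.integer(event)
  n <- length(h)
  if (length(time) != n || length(event) != n)
    stop("'h', 'time' and 'event' must have equal length")
  events <- which(event == 1L)
  if (length(events) == 0L)
    stop("no events in the batch: Cox partial likelihood undefined")
  ## sort by decreasing time; cumulative logsumexp gives each risk set
  ord <- order(time, decreasing = TRUE)
  hs <- h[ord]
  m <- max(hs)                          # shift for numerical stability
  cumlse <- log(cumsum(exp(hs - m))) + m
  ## with ties, every tied sample must see the full tied risk set:
  ## take, for each position, the cumlse at the last index of its tie group
  ts <- time[ord]
  lastOfTie <- vapply(seq_len(n), function(i)
    max(which(ts == ts[i])), integer(1))
  lse <- cumlse[lastOfTie]
  isEvent <- event[ord] == 1L
  -sum(hs[isEvent] - lse[isEvent]) / length(events)
}

## Gradient of coxNLL wrt h (same ordering as input). Internal.
coxNLLGrad <- function(h, time, event) {
  n <- length(h)
  events <- which(event == 1L)
  Nob <- length(events)
  g <- numeric(n)
  eh <- exp(h - max(h))
  for (i in events) {
    rs <- which(time >= time[i])
    w <- eh[rs] / sum(eh[rs])
    g[i] <- g[i] - 1 / Nob
    g[rs] <- g[rs] + w / Nob
  }
  g
}

## Gradient of crossEntropyLoss wrt logits. Internal.
crossEntropyGrad <- function(logits, labels) {
  n <- nrow(logits)
  m <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  p <- exp(logits - m)
  p <- p / rowSums(p)
  p[cbind(seq_len(n), as.integer(labels) + 1L)] <-
    p[cbind(seq_len(n), as.integer(labels) + 1L)] - 1
  p / n
}

## Gradient of mseRecon wrt xhat. Internal.
mseReconGrad <- function(x, xhat) 2 * (xhat - x) / length(x)
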