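#' Construct a training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 0.001
#' and 200 epochs; batch size 32 for classification and 128 for
#' survival. For cross-modality (consensus) integration the three
#' training phases get `epochsPerCrossStep` epochs each (per-modality
#' reconstruction, cross-modality reconstruction, task training);
#' the default `(100, 100, 200)` keeps the 200-epoch task budget while
#' giving the two representation phases equal time.
#'
#' @param endpoint `"classification"` or `"survival"`
#' @param batchSize minibatch size (default 32 classification /
#'   128 survival)
#' @param learningRate Adam learning rate
#' @param epochs training epochs for single/concat integration
#' @param seed integer seed controlling initialization and batch order
#' @param optimizer only `"adam"` is supported
#' @param epochsPerCrossStep integer triple for the three CrossAE phases
#' @return a [TrainConfig-class]
#' @examples
#' trainConfig("survival", epochs = 50)
#' @export
trainConfig <- function(endpoint = c("classification", "survival"),
                        batchSize = NULL, learningRate = 0.001,
                        epochs = 200L, seed = 1L, optimizer = "adam",
                        epochsPerCrossStep = c(100L, 100L, 200L)) {
  endpoint <- match.arg(endpoint)
  if (is.null(batchSize))
    batchSize <- if (endpoint == "classification") 32L else 128L
  new("TrainConfig", batchSize = as.integer(batchSize),
      learningRate = learningRate, epochs = as.integer(epochs),
      seed = as.integer(seed), optimizer = optimizer, endpoint = endpoint,
      epochsPerCrossStep = as.integer(epochsPerCrossStep))
}

## ---------------------------------------------------------------------------
## Shared training engine
## ---------------------------------------------------------------------------

## integration decides the latent fusion fed to the task head ("single" and
## "concat" concatenate — identical for one modality — "cross" averages) and
## the training schedule (interleaved recon/task passes vs the three
## sequential cross phases).
trainEngine <- function(specs, xs, outcome, config, integration,
                        modalities, valXs = NULL, valOutcome = NULL,
                        interleave = FALSE) {
  M <- length(xs)
  xs <- lapply(xs, as.matrix)
  n <- nrow(xs[[1]])
  if (any(vapply(xs, nrow, integer(1)) != n))
    stop("modalities are misaligned: differing sample counts")
  for (m in seq_len(M))
    if (ncol(xs[[m]]) != specs[[m]]@inputDim)
      stop("modality ", m, " has ", ncol(xs[[m]]),
           " features but its spec expects ", specs[[m]]@inputDim)
  endpoint <- config@endpoint
  classification <- endpoint == "classification"
  if (classification) {
    labels <- as.integer(outcome)
    stopifnot(length(labels) == n)
    nClasses <- max(labels) + 1L
  } else {
    surv <- outcome
    if (!is(surv, "SurvivalData"))
      stop("survival training requires a SurvivalData outcome")
    stopifnot(length(surv) == n)
    if (sum(eventIndicator(surv)) == 0L)
      stop("no events in the training data: survival loss undefined")
    time <- survTimes(surv); event <- eventIndicator(surv)
    nClasses <- 0L
  }
  latentDims <- vapply(specs, function(s) s@hiddenDim, integer(1))
  fuseKind <- if (integration == "cross") "average" else "concat"
  if (fuseKind == "average" && length(unique(latentDims)) > 1L)
    stop("cross integration requires equal latent dims across modalities")
  headIn <- if (fuseKind == "concat") sum(latentDims) else latentDims[1]
  encN <- paste0("enc", seq_len(M))
  decN <- paste0("dec", seq_len(M))
  colEnd <- cumsum(latentDims)
  colStart <- colEnd - latentDims + 1L

  withSeed(config@seed, {
    nets <- list()
    for (m in seq_len(M)) {
      p <- initAutoencoderParams(specs[[m]])
      nets[[encN[m]]] <- p$encoder
      nets[[decN[m]]] <- p$decoder
    }
    nets$head <- initHeadParams(headIn, endpoint, nClasses)
    optRecon <- adamInit(nets)
    optCross <- adamInit(nets)
    optTask <- adamInit(nets)
    lr <- config@learningRate
    bs <- config@batchSize

    makeBatches <- function() {
      idx <- sample.int(n)
      split(idx, ceiling(seq_along(idx) / bs))
    }

    reconPass <- function() {
      tot <- 0
      for (b in makeBatches()) {
        grads <- list(); loss <- 0
        for (m in seq_len(M)) {
          xb <- xs[[m]][b, , drop = FALSE]
          fe <- mlpForward(nets[[encN[m]]], xb, cache = TRUE)
          fd <- mlpForward(nets[[decN[m]]], fe$out, cache = TRUE)
          loss <- loss + mean((xb - fd$out)^2)
          bd <- mlpBackward(nets[[decN[m]]], fd, mseReconGrad(xb, fd$out))
          be <- mlpBackward(nets[[encN[m]]], fe, bd$dX)
          grads[[decN[m]]] <- bd[c("gW", "gb")]
          grads[[encN[m]]] <- be[c("gW", "gb")]
        }
        adamStep(nets, grads, optRecon, lr)
        tot <- tot + loss * length(b)
      }
      tot / n
    }

    crossPass <- function() {
      tot <- 0
      for (b in makeBatches()) {
        fes <- lapply(seq_len(M), function(m)
          mlpForward(nets[[encN[m]]], xs[[m]][b, , drop = FALSE],
                     cache = TRUE))
        grads <- list(); dZ <- vector("list", M); loss <- 0
        for (a in seq_len(M)) for (s in seq_len(M)) if (a != s) {
          fd <- mlpForward(nets[[decN[a]]], fes[[s]]$out, cache = TRUE)
          xa <- xs[[a]][b, , drop = FALSE]
          loss <- loss + mean((xa - fd$out)^2)
          bd <- mlpBackward(nets[[decN[a]]], fd, mseReconGrad(xa, fd$out))
          grads[[decN[a]]] <- addGrads(grads[[decN[a]]], bd[c("gW", "gb")])
          dZ[[s]] <- if (is.null(dZ[[s]])) bd$dX else dZ[[s]] + bd$dX
        }
        for (m in seq_len(M)) {
          bm <- mlpBackward(nets[[encN[m]]], fes[[m]], dZ[[m]])
          grads[[encN[m]]] <- bm[c("gW", "gb")]
        }
        adamStep(nets, grads, optCross, lr)
        tot <- tot + loss * length(b)
      }
      tot / n
    }

    taskPass <- function() {
      tot <- 0; used <- 0L
      for (b in makeBatches()) {
        if (!classification && sum(event[b]) == 0L) next  # no risk set
        fes <- lapply(seq_len(M), function(m)
          mlpForward(nets[[encN[m]]], xs[[m]][b, , drop = FALSE],
                     cache = TRUE))
        zs <- lapply(fes, `[[`, "out")
        zf <- if (fuseKind == "concat") do.call(cbind, zs)
              else Reduce(`+`, zs) / M
        fh <- mlpForward(nets$head, zf, cache = TRUE)
        if (classification) {
          loss <- crossEntropyLoss(fh$out, labels[b])
          dOut <- crossEntropyGrad(fh$out, labels[b])
        } else {
          h <- as.vector(fh$out)
          loss <- coxNLL(h, time[b], event[b])
          dOut <- matrix(coxNLLGrad(h, time[b], event[b]), ncol = 1)
        }
        bh <- mlpBackward(nets$head, fh, dOut)
        grads <- list(head = bh[c("gW", "gb")])
        for (m in seq_len(M)) {
          dZm <- if (fuseKind == "concat")
            bh$dX[, colStart[m]:colEnd[m], drop = FALSE]
          else bh$dX / M
          bm <- mlpBackward(nets[[encN[m]]], fes[[m]], dZm)
          grads[[encN[m]]] <- bm[c("gW", "gb")]
        }
        adamStep(nets, grads, optTask, lr)
        tot <- tot + loss * length(b); used <- used + length(b)
      }
      if (used == 0L) NA_real_ else tot / used
    }

    valMetric <- function() {
      zs <- lapply(seq_len(M), function(m)
        mlpForward(nets[[encN[m]]], valXs[[m]]))
      zf <- if (fuseKind == "concat") do.call(cbind, zs)
            else Reduce(`+`, zs) / length(zs)
      out <- mlpForward(nets$head, zf)
      if (classification) {
        mean(max.col(out, ties.method = "first") - 1L ==
               as.integer(valOutcome))
      } else {
        concordanceIndex(as.vector(out), survTimes(valOutcome),
                         eventIndicator(valOutcome))
      }
    }

    trace <- list()
    best <- -Inf; bestNets <- NULL; bestEpoch <- NA_integer_
    track <- !is.null(valXs)
    record <- function(epoch, phase, recon = NA_real_, cross = NA_real_,
                       task = NA_real_, val = NA_real_) {
      trace[[length(trace) + 1L]] <<- data.frame(
        epoch = epoch, phase = phase, recon = recon, cross = cross,
        task = task, val = val)
    }
    afterTask <- function(epoch, phase, recon, cross, task) {
      v <- NA_real_
      if (track) {
        v <- valMetric()
        if (!is.na(v) && v > best) {
          best <<- v; bestNets <<- deepCopyNets(nets); bestEpoch <<- epoch
        }
      }
      record(epoch, phase, recon, cross, task, v)
    }

    if (integration != "cross") {
      for (e in seq_len(config@epochs)) {
        r <- reconPass()
        tk <- taskPass()
        afterTask(e, "interleaved", recon = r, cross = NA_real_, task = tk)
      }
    } else if (interleave) {
      for (e in seq_len(config@epochs)) {
        r <- reconPass(); cr <- crossPass(); tk <- taskPass()
        afterTask(e, "interleaved", recon = r, cross = cr, task = tk)
      }
    } else {
      ep <- config@epochsPerCrossStep
      for (e in seq_len(ep[1]))
        record(e, "recon", recon = reconPass())
      for (e in seq_len(ep[2]))
        record(ep[1] + e, "cross", cross = crossPass())
      for (e in seq_len(ep[3]))
        afterTask(ep[1] + ep[2] + e, "task", recon = NA_real_,
                  cross = NA_real_, task = taskPass())
    }

    finalNets <- if (track && !is.null(bestNets)) bestNets else nets
    params <- list(
      modalities = lapply(seq_len(M), function(m)
        list(encoder = finalNets[[encN[m]]], decoder = finalNets[[decN[m]]])),
      head = finalNets$head)
    tr <- if (length(trace)) do.call(rbind, trace) else
      data.frame(epoch = integer(0), phase = character(0),
                 recon = numeric(0), cross = numeric(0), task = numeric(0),
                 val = numeric(0))
    bundle <- new("ModelBundle", specs = specs, params = params,
                  integration = integration, endpoint = endpoint,
                  modalities = modalities, nClasses = as.integer(nClasses),
                  trace = tr)
    attr(bundle@trace, "bestEpoch") <- bestEpoch
    bundle
  })
}

#' Train the integration models
#'
#' `trainSingle()` trains one autoencoder plus task head by alternating,
#' every epoch, a full minibatch pass of reconstruction updates
#' (encoder + decoder, mean-squared-error loss) with a full pass of task
#' updates (encoder + head, cross-entropy or Cox partial-likelihood
#' loss). `trainConcat()` (complementary integration) does the same with
#' one independent autoencoder per modality, summing the per-modality
#' reconstruction losses and feeding the concatenated latent features to
#' the head. `trainCross()` (consensus integration) trains in three
#' sequential phases: per-modality reconstruction, cross-modality
#' reconstruction (each decoder learns to reconstruct its modality from
#' the other modalities' latent features), and task training on the
#' element-wise average of the latent features; `interleave = TRUE`
#' instead runs all three passes every epoch for `epochs` epochs.
#'
#' Survival minibatches with zero events are skipped (their partial
#' likelihood is undefined). When validation data are supplied, the
#' per-epoch validation metric (accuracy or concordance index) is
#' recorded and the returned bundle carries the parameters of the best
#' validation epoch; otherwise the final parameters.
#'
#' @param spec,specs a [NetworkSpec-class] (or list of them, one per
#'   modality)
#' @param x,xs samples x features matrix (or list of matrices, aligned
#'   on samples)
#' @param outcome integer class labels in `0..C-1`, or a
#'   [SurvivalData-class]
#' @param config a [TrainConfig-class]
#' @param modality,modalities modality name tag(s)
#' @param valX,valXs,valOutcome optional validation data for per-epoch
#'   metric tracking and checkpoint selection
#' @param interleave CrossAE only: run the three phases within each
#'   epoch instead of sequentially
#' @return a trained [ModelBundle-class]; its `trace` slot holds the
#'   per-epoch losses (and validation metric when tracked)
#' @name trainers
#' @export
trainSingle <- function(spec, x, outcome, config, modality = "m1",
                        valX = NULL, valOutcome = NULL) {
  trainEngine(list(spec), list(x), outcome, config, "single", modality,
              valXs = if (is.null(valX)) NULL else list(valX),
              valOutcome = valOutcome)
}

#' @rdname trainers
#' @export
trainConcat <- function(specs, xs, outcome, config,
                        modalities = paste0("m", seq_along(xs)),
                        valXs = NULL, valOutcome = NULL) {
  trainEngine(specs, xs, outcome, config, "concat", modalities,
              valXs = valXs, valOutcome = valOutcome)
}

#' @rdname trainers
#' @export
trainCross <- function(specs, xs, outcome, config,
                       modalities = paste0("m", seq_along(xs)),
                       valXs = NULL, valOutcome = NULL,
                       interleave = FALSE) {
  if (length(xs) < 2L)
    stop("cross integration needs >= 2 modalities ",
         "(cross-modality reconstruction is undefined for one)")
  trainEngine(specs, xs, outcome, config, "cross", modalities,
              valXs = valXs, valOutcome = valOutcome,
              interleave = interleave)
}
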