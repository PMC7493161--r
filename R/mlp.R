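## Internal fully connected network core: parameter init, forward pass with
## cache, backward pass, and an Adam optimizer operating on lists of nets.
## Parameters are plain lists so bundles serialize with saveRDS and copy
## cheaply for checkpointing.

## A "net" is list(W = list of d_in x d_out matrices, b = list of vectors,
## act = character per layer in {"relu", "linear", "sigmoid"}).

mlpInit <- function(widths, acts) {
  stopifnot(length(acts) == length(widths) - 1L)
  L <- length(acts)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- 1 / sqrt(widths[l])                 # uniform fan-in scheme
    W[[l]] <- matrix(runif(widths[l] * widths[l + 1L], -lim, lim),
                     widths[l], widths[l + 1L])
    b[[l]] <- runif(widths[l + 1L], -lim, lim)
  }
  list(W = W, b = b, act = acts)
}

actCodes <- function(act) {
  code <- match(act, c("linear", "relu", "sigmoid")) - 1L
  if (anyNA(code)) stop("unknown activation: ", act[is.na(code)][1])
  code
}

## Forward pass (C++ core). With cache = TRUE returns list(out, X, H) where
## H keeps the per-layer output activations needed for backprop.
mlpForward <- function(net, X, cache = FALSE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.double(X)) storage.mode(X) <- "double"
  res <- mlp_forward_cpp(net$W, net$b, actCodes(net$act), X, cache)
  if (cache) list(out = res$out, X = X, H = res$H) else res$out
}

## Backward pass. dOut is the gradient wrt the network output (post
## activation); fwd is the cached forward pass. Returns list(gW, gb, dX).
mlpBackward <- function(net, fwd, dOut) {
  if (!is.matrix(dOut)) dOut <- as.matrix(dOut)
  if (!is.double(dOut)) storage.mode(dOut) <- "double"
  mlp_backward_cpp(net$W, actCodes(net$act), fwd$X, fwd$H, dOut)
}

## ---------------------------------------------------------------------------
## Adam over a named list of nets
## ---------------------------------------------------------------------------

## Optimizer state lives in an environment; moment buffers are fresh
## allocations owned exclusively by the optimizer so the C kernel can update
## parameters and moments in place (no per-step temporaries).
adamInit <- function(nets) {
  zero <- function(x) { x[] <- 0; x }
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$state <- lapply(nets, function(net) list(
    mW = lapply(net$W, zero), vW = lapply(net$W, zero),
    mb = lapply(net$b, zero), vb = lapply(net$b, zero)))
  opt
}

## nets: named list of nets; grads: named list of list(gW, gb) (missing
## entries are skipped). Updates the parameter matrices of `nets` in place.
adamStep <- function(nets, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- opt$state[[nm]]
    net <- nets[[nm]]
    for (l in seq_along(net$W)) {
      adam_update_inplace(net$W[[l]], st$mW[[l]], st$vW[[l]], g$gW[[l]],
                          lr, beta1, beta2, eps, c1, c2)
      adam_update_inplace(net$b[[l]], st$mb[[l]], st$vb[[l]], g$gb[[l]],
                          lr, beta1, beta2, eps, c1, c2)
    }
  }
  invisible(NULL)
}

## Deep copy of a nets list so a checkpoint snapshot cannot alias parameter
## matrices that the in-place optimizer keeps updating.
deepCopyNets <- function(x) {
  rapply(x, function(v) if (is.numeric(v)) v + 0 else v, how = "replace")
}

## Accumulate gradient lists (same shapes): a + b
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (l in seq_along(a$gW)) {
    a$gW[[l]] <- a$gW[[l]] + b$gW[[l]]
    a$gb[[l]] <- a$gb[[l]] + b$gb[[l]]
  }
  a
}
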