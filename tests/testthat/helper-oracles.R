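## Independent brute-force oracles used to cross-check the implementation.

## Cox negative log partial likelihood by explicit risk-set enumeration.
bruteCoxNLL <- function(h, time, event) {
  ev <- which(event == 1)
  s <- 0
  for (i in ev) {
    rs <- which(time >= time[i])
    s <- s + h[i] - log(sum(exp(h[rs])))
  }
  -s / length(ev)
}

## Concordance index by explicit enumeration of all ordered pairs.
bruteCIndex <- function(h, time, event) {
  conc <- 0; comp <- 0
  n <- length(h)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < time[j]) {
      comp <- comp + 1
      if (h[i] > h[j]) conc <- conc + 1
      else if (h[i] == h[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

## Per-class confusion-matrix metrics, written independently of the
## implementation (explicit loops over classes).
bruteClassMetrics <- function(pred, truth) {
  classes <- sort(unique(c(pred, truth)))
  prec <- rec <- w <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(pred == cl & truth == cl)
    prec[k] <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec[k] <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    w[k] <- sum(truth == cl) / length(truth)
  }
  c(accuracy = mean(pred == truth),
    weighted_precision = sum(w * prec),
    weighted_recall = sum(w * rec))
}

## Central finite difference of f at x.
numGrad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

## Small [0, 1]-scaled two-class dataset that a small network separates.
makeToyClassification <- function(n = 50, p = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * p, 0), n / 2),
             matrix(rnorm(n / 2 * p, 2), n / 2))
  x <- (x - min(x)) / diff(range(x))
  list(x = x, y = rep(0:1, each = n / 2))
}
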