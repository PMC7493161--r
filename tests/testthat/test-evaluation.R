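test_that("classification metrics reproduce the hand confusion matrix", {
  expect_equal(unname(classificationMetrics(c(1, 1), c(1, 1))),
               c(1, 1, 1))
  m <- classificationMetrics(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(unname(m["accuracy"]), 0.75)
  expect_equal(unname(m["weighted_recall"]), 0.5 * 0.5 + 0.5 * 1.0)
  expect_equal(unname(m["weighted_precision"]), 0.5 * 1.0 + 0.5 * (2 / 3))
  ## all-one-class predictions on balanced binary truth
  m2 <- classificationMetrics(rep(0, 10), rep(0:1, 5))
  expect_equal(unname(m2["accuracy"]), 0.5)
  ## a class absent from predictions contributes precision 0
  expect_equal(unname(m2["weighted_precision"]), 0.5 * 0.5 + 0.5 * 0)
  expect_error(classificationMetrics(integer(0), integer(0)), "non-empty")
})

test_that("classification metrics agree with an independent oracle", {
  for (rep in 1:200) {
    set.seed(rep)
    n <- sample(5:40, 1)
    C <- sample(2:5, 1)
    truth <- sample(0:(C - 1), n, replace = TRUE)
    pred <- sample(0:(C - 1), n, replace = TRUE)
    expect_equal(classificationMetrics(pred, truth),
                 bruteClassMetrics(pred, truth))
  }
})

test_that("concordance index counts comparable pairs with 0.5 ties", {
  ## enumerated example: comparable pairs (1,2),(1,3),(1,4),(3,4)
  expect_equal(concordanceIndex(c(3, 1, 0, 2), c(2, 4, 6, 8),
                                c(1, 0, 1, 0)), 0.75)
  ## perfect anti-ordering, all events
  tm <- c(1, 2, 3, 4, 5)
  expect_equal(concordanceIndex(rev(tm), tm, rep(1, 5)), 1)
  ## constant hazards are chance level under the tie convention
  expect_equal(concordanceIndex(rep(0, 5), tm, rep(1, 5)), 0.5)
  expect_error(concordanceIndex(1:3, 1:3, c(0, 0, 0)), "comparable")
})

test_that("concordance index equals the all-pairs oracle exactly", {
  for (rep in 1:200) {
    set.seed(1000 + rep)
    n <- sample(3:50, 1)
    tm <- sample(1:20, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    h <- round(rnorm(n), 1)              # induce hazard ties
    if (sum(ev == 1 & tm < max(tm)) == 0) { ev[which.min(tm)] <- 1L }
    expect_identical(concordanceIndex(h, tm, ev), bruteCIndex(h, tm, ev))
  }
})

test_that("concordance index has the complement and invariance properties", {
  set.seed(8)
  n <- 60
  h <- rnorm(n)                          # continuous: no hazard ties
  tm <- rexp(n, exp(h)); ev <- rbinom(n, 1, 0.7); ev[1] <- 1L
  ci <- concordanceIndex(h, tm, ev)
  expect_equal(ci + concordanceIndex(-h, tm, ev), 1)
  ## invariant under strictly increasing transforms of the hazard
  expect_equal(concordanceIndex(exp(h), tm, ev), ci)
  expect_equal(concordanceIndex(3 * h + 2, tm, ev), ci)
})

test_that("concordance index matches the survival package", {
  skip_if_not_installed("survival")
  set.seed(2)
  n <- 40
  h <- rnorm(n); tm <- rexp(n, exp(h)); ev <- rbinom(n, 1, 0.7)
  ev[1] <- 1L
  sv <- survival::concordance(survival::Surv(tm, ev) ~ h)$concordance
  expect_equal(concordanceIndex(h, tm, ev), 1 - sv, tolerance = 1e-12)
})

test_that("paired latent distances are Euclidean and symmetric", {
  expect_equal(pairedHiddenDistance(matrix(0, 1, 2),
                                    matrix(c(3, 4), 1, 2))$mean, 5)
  z <- matrix(rnorm(20), 5, 4)
  d0 <- pairedHiddenDistance(z, z)
  expect_true(all(d0$distances == 0))
  w <- matrix(rnorm(20), 5, 4)
  expect_equal(pairedHiddenDistance(z, w)$distances,
               pairedHiddenDistance(w, z)$distances)
  expect_error(pairedHiddenDistance(z, matrix(0, 5, 3)), "dimensions")
  expect_named(pairedHiddenDistance(z, w), c("distances", "mean",
                                             "quartiles"))
})

test_that("the distance report has one row per sample per modality pair", {
  toy <- makeToyClassification(n = 24, p = 6, seed = 5)
  sp <- networkSpec(6, hiddenDim = 3)
  cfg <- trainConfig("classification", epochs = 2, seed = 1, batchSize = 8)
  b <- trainConcat(list(sp, sp), list(toy$x, toy$x), toy$y, cfg,
                   modalities = c("m1", "m2"))
  rep <- pairedDistanceReport(b, list(toy$x, toy$x))
  expect_equal(nrow(rep), 24)
  expect_equal(unique(rep$pair), "m1+m2")
  expect_equal(unique(rep$integration), "concat")
})
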