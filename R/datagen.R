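#' Configuration for the synthetic multi-omics survival generator
#'
#' The generator emulates a multi-modality omics study: a set of
#' consensus latent factors shared by every modality, modality-unique
#' latent factors, random linear loadings, feature noise, and
#' right-censored survival times tied to the latent factors through a
#' linear-risk proportional-hazards model with exponential baseline.
#'
#' @param nSamples number of samples
#' @param featuresPerModality integer vector, observed features per
#'   modality (its length sets the number of modalities unless
#'   `nModalities` is given)
#' @param dimShared number of shared (consensus) latent factors
#' @param dimUnique modality-unique latent factors per modality
#' @param effectShared,effectUnique non-negative risk-coefficient
#'   magnitudes of the shared and unique factors
#' @param noiseSd feature-level Gaussian noise sd (before \[0,1\] scaling)
#' @param censoringFraction target expected censored fraction, in \[0, 1)
#' @param baselineHazard baseline event rate per day (> 0)
#' @param nModalities number of modalities (defaults to
#'   `length(featuresPerModality)`)
#' @param seed integer seed
#' @return a validated configuration list for [simulateOmicsSurvival()]
#' @examples
#' cfg <- syntheticOmicsConfig(nSamples = 100, seed = 7)
#' @export
syntheticOmicsConfig <- function(nSamples = 600L,
                                 featuresPerModality = c(200L, 200L),
                                 dimShared = 5L, dimUnique = 5L,
                                 effectShared = 1, effectUnique = 0.5,
                                 noiseSd = 0.3, censoringFraction = 0.3,
                                 baselineHazard = 0.002,
                                 nModalities = length(featuresPerModality),
                                 seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples),
              featuresPerModality = as.integer(featuresPerModality),
              dimShared = as.integer(dimShared),
              dimUnique = as.integer(dimUnique),
              effectShared = effectShared, effectUnique = effectUnique,
              noiseSd = noiseSd, censoringFraction = censoringFraction,
              baselineHazard = baselineHazard,
              nModalities = as.integer(nModalities),
              seed = as.integer(seed))
  if (cfg$nSamples < 1L || cfg$dimShared < 1L || cfg$dimUnique < 1L ||
      any(cfg$featuresPerModality < 1L))
    stop("all counts in the configuration must be positive")
  if (length(cfg$featuresPerModality) < cfg$nModalities)
    stop("'featuresPerModality' is shorter than the number of modalities")
  if (cfg$effectShared < 0 || cfg$effectUnique < 0 || cfg$noiseSd < 0)
    stop("effects and noiseSd must be non-negative")
  if (cfg$censoringFraction < 0 || cfg$censoringFraction >= 1)
    stop("'censoringFraction' must lie in [0, 1)")
  if (cfg$baselineHazard <= 0) stop("'baselineHazard' must be positive")
  cfg
}

## Solve for the censoring rate c such that the expected censored fraction
## E[ c / (c + lambda_i) ] over samples equals the target.
censoringRate <- function(lambda, target) {
  f <- function(logc) mean(exp(logc) / (exp(logc) + lambda)) - target
  exp(uniroot(f, lower = log(min(lambda)) - 20,
              upper = log(max(lambda)) + 20)$root)
}

## Per-column min-max scaling to [0, 1]; constant columns map to 0.
minmaxColumns <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  out <- sweep(sweep(x, 2, lo, "-"), 2, span, "/")
  out[, hi == lo] <- 0
  out
}

#' Simulate multi-omics matrices with paired survival outcomes
#'
#' Draws standard-normal shared factors `u_shared` (common to all
#' modalities) and modality-unique factors `u_m`; each modality's
#' observed matrix is `[u_shared, u_m] %*% loadings + noise`, min-max
#' scaled per feature to \[0, 1\]. The true linear risk is
#' `effectShared * (u_shared w_s) + effectUnique * sum_m (u_m w_m)`
#' with fixed unit-norm weights; event times are exponential with rate
#' `baselineHazard * exp(risk)` and censoring times are exponential with
#' a rate solved numerically so the expected censored fraction matches
#' `censoringFraction`.
#'
#' @param config output of [syntheticOmicsConfig()]
#' @return list with `omics` (list of [OmicsMatrix-class]), `survival`
#'   (a [SurvivalData-class]) and `trueRisk` (numeric; enables an oracle
#'   concordance index)
#' @examples
#' sim <- simulateOmicsSurvival(syntheticOmicsConfig(nSamples = 50))
#' sim$omics[[1]]
#' sim$survival
#' @export
simulateOmicsSurvival <- function(config = syntheticOmicsConfig()) {
  cfg <- do.call(syntheticOmicsConfig, config)  # re-validate
  M <- cfg$nModalities
  n <- cfg$nSamples
  withSeed(cfg$seed, {
    uShared <- matrix(rnorm(n * cfg$dimShared), n)
    uUnique <- lapply(seq_len(M), function(m)
      matrix(rnorm(n * cfg$dimUnique), n))
    wS <- rnorm(cfg$dimShared); wS <- wS / sqrt(sum(wS^2))
    wU <- lapply(seq_len(M), function(m) {
      w <- rnorm(cfg$dimUnique); w / sqrt(sum(w^2))
    })
    risk <- as.vector(cfg$effectShared * (uShared %*% wS))
    for (m in seq_len(M))
      risk <- risk + cfg$effectUnique * as.vector(uUnique[[m]] %*% wU[[m]])
    sid <- sprintf("S%04d", seq_len(n))
    omics <- lapply(seq_len(M), function(m) {
      p <- cfg$featuresPerModality[m]
      k <- cfg$dimShared + cfg$dimUnique
      loadings <- matrix(rnorm(k * p), k, p) / sqrt(k)
      x <- cbind(uShared, uUnique[[m]]) %*% loadings +
        matrix(rnorm(n * p, 0, cfg$noiseSd), n, p)
      x <- minmaxColumns(x)
      rownames(x) <- sid
      colnames(x) <- sprintf("M%d_F%04d", m, seq_len(p))
      OmicsMatrix(x, modality = sprintf("Mod%d", m))
    })
    lambda <- cfg$baselineHazard * exp(risk)
    eventTime <- rexp(n, lambda)
    if (cfg$censoringFraction == 0) {
      time <- eventTime
      event <- rep(1L, n)
    } else {
      cRate <- censoringRate(lambda, cfg$censoringFraction)
      censTime <- rexp(n, cRate)
      event <- as.integer(eventTime <= censTime)
      time <- pmin(eventTime, censTime)
    }
    list(omics = omics,
         survival = SurvivalData(sid, time, event),
         trueRisk = risk)
  })
}

## ---------------------------------------------------------------------------
## Delimited-text interchange
## ---------------------------------------------------------------------------

#' Read/write omics matrices and survival tables as CSV
#'
#' The matrix format has samples in rows: the first column `sample_id`,
#' remaining columns named by feature id. The survival format has three
#' columns `sample_id`, `time`, `event`.
#'
#' @param x an [OmicsMatrix-class] or [SurvivalData-class]
#' @param path file path
#' @param modality modality tag attached on reading
#' @return `readOmicsMatrix()` an [OmicsMatrix-class];
#'   `readSurvivalData()` a [SurvivalData-class]; the writers return
#'   `path` invisibly
#' @name omicsIO
#' @examples
#' om <- OmicsMatrix(matrix(rnorm(6), 2, 3), modality = "miRNA")
#' f <- tempfile(fileext = ".csv")
#' writeOmicsMatrix(om, f)
#' readOmicsMatrix(f, modality = "miRNA")
NULL

#' @rdname omicsIO
#' @export
writeOmicsMatrix <- function(x, path) {
  v <- omicsValues(x)
  df <- data.frame(sample_id = sampleIds(x), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname omicsIO
#' @export
readOmicsMatrix <- function(path, modality = "unnamed") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("first column of an omics CSV must be 'sample_id'")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  OmicsMatrix(v, modality = modality)
}

#' @rdname omicsIO
#' @export
writeSurvivalData <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname omicsIO
#' @export
readSurvivalData <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival CSV must have columns sample_id, time, event")
  SurvivalData(df$sample_id, df$time, df$event)
}
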