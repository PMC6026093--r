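#' Simulate a stationary MVAR process
#'
#' Generates `w_n = sum_r A^r w_{n-r} + xi_n` with Gaussian innovations of
#' covariance `noiseCov`.  The first `burnIn` samples (default 10 x order)
#' are discarded so the returned series is free of start-up transients.
#'
#' @param model an [MVARModel-class] coupling specification.
#' @param nSamples number of samples to return (after burn-in).
#' @param seed optional RNG seed for reproducibility.
#' @param burnIn transient samples to discard (default `10 * order`).
#' @return An [EEGSignal-class] of `nSamples` rows.
#' @examples
#' m <- MVARModel(list(matrix(c(.5, .4, 0, .5), 2, 2)))
#' sig <- simulateMVAR(m, 1000, seed = 1)
#' @export
simulateMVAR <- function(model, nSamples, seed = NULL, burnIn = 10L * model@order) {
  stopifnot(is(model, "MVARModel"))
  rho <- spectralRadius(model)
  if (rho >= 1)
    stop(sprintf("non-stationary coupling spec: companion spectral radius %.4f >= 1", rho))
  ch <- tryCatch(chol(model@noiseCov),
                 error = function(e) stop("noiseCov is not positive definite"))
  if (nSamples <= 10L * model@order)
    stop("nSamples must exceed 10 x order")
  if (!is.null(seed)) set.seed(seed)
  m <- model@order
  nc <- nChannels(model)
  ntot <- nSamples + burnIn + m
  E <- matrix(stats::rnorm(ntot * nc), ntot, nc) %*% ch
  W <- E
  A <- model@A
  for (n in (m + 1L):ntot) {
    acc <- E[n, ]
    for (r in seq_len(m))
      acc <- acc + A[[r]] %*% W[n - r, ]
    W[n, ] <- acc
  }
  EEGSignal(W[(ntot - nSamples + 1L):ntot, , drop = FALSE],
            samplingRate(model), channelNames(model))
}

#' Simulate a lagged two-channel mixture
#'
#' Channel 2 is channel 1 delayed by `lag` samples plus independent Gaussian
#' noise at the requested signal-to-noise (variance) ratio.  An optional
#' instantaneous mixing matrix can be applied to both channels, providing the
#' zero-delay mixing stress test that the phase slope index is designed to be
#' insensitive to.
#'
#' @param nSamples number of samples.
#' @param lag delay in samples (>= 0).
#' @param snr variance ratio signal/noise; `Inf` means no additive noise.
#' @param samplingRate Hz (default 250).
#' @param mixing optional 2 x 2 instantaneous mixing matrix applied to the
#'   (source, delayed) pair.
#' @param seed optional RNG seed.
#' @return An [EEGSignal-class] with channels `src`, `dst`.
#' @export
simulateLaggedMixture <- function(nSamples, lag, snr = Inf, samplingRate = 250,
                                  mixing = NULL, seed = NULL) {
  if (lag < 0) stop("lag must be >= 0")
  if (lag >= nSamples) stop("lag must be smaller than nSamples")
  if (!is.null(seed)) set.seed(seed)
  src <- stats::rnorm(nSamples + lag)
  x1 <- src[lag + seq_len(nSamples)]
  x2 <- src[seq_len(nSamples)]           # x2(t) = x1(t - lag)
  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive")
    x2 <- x2 + stats::rnorm(nSamples, sd = sqrt(1 / snr))
  }
  x <- cbind(src = x1, dst = x2)
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (any(dim(mixing) != 2L)) stop("mixing must be 2 x 2")
    x <- x %*% t(mixing)
    colnames(x) <- c("src", "dst")
  }
  EEGSignal(x, samplingRate)
}

## ---- cohort generation ------------------------------------------------

#' Default synthetic-cohort configuration
#'
#' The defaults reproduce the study conditions the pipeline targets: 26
#' subjects, 4 emotional conditions at 250 Hz over an 8-channel symmetric
#' 10/20 montage, PSS-14 totals with mean 24 and SD 6.7 grouped by the
#' mu +/- sigma/2 rule, and directed coupling that differs by condition
#' (arousal modulates frontal->central gain, valence flips a left/right
#' parietal asymmetry) and, in the resting state, by stress group.
#'
#' @param nSubjects number of subjects (default 26).
#' @param nConditions number of emotional conditions, at most 4 (default 4).
#' @param samplingRate sampling rate in Hz (default 250).
#' @param segmentDuration seconds of EEG per emotional condition (default 60).
#' @param restingDuration seconds of resting-state EEG (default 60).
#' @param stressFraction target fraction of subjects in each of the stressed
#'   and stress-free groups (default 0.31, the mass outside mu +/- sigma/2
#'   of a Gaussian).
#' @param effectSize relative perturbation of stressed subjects' coupling
#'   gains (default 0.5; 0 gives a null cohort).
#' @param samNoise maximum absolute integer jitter added to the nominal SAM
#'   response of each condition (default 1).
#' @param pssMean,pssSd target mean and SD of the PSS-14 totals
#'   (defaults 24 and 6.7).
#' @param channels montage (default F3 F4 C3 C4 P3 P4 T7 T8).
#' @param seed RNG seed (default 1).
#' @return A list with class `CohortConfig`.
#' @export
cohortConfig <- function(nSubjects = 26L, nConditions = 4L, samplingRate = 250,
                         segmentDuration = 60, restingDuration = 60,
                         stressFraction = 0.31, effectSize = 0.5,
                         samNoise = 1L, pssMean = 24, pssSd = 6.7,
                         channels = c("F3", "F4", "C3", "C4", "P3", "P4", "T7", "T8"),
                         seed = 1L) {
  cfg <- list(nSubjects = as.integer(nSubjects),
              nConditions = as.integer(nConditions),
              samplingRate = samplingRate,
              segmentDuration = segmentDuration,
              restingDuration = restingDuration,
              stressFraction = stressFraction, effectSize = effectSize,
              samNoise = as.integer(samNoise),
              pssMean = pssMean, pssSd = pssSd,
              channels = channels, seed = as.integer(seed))
  stopifnot(cfg$nConditions >= 1L, cfg$nConditions <= 4L,
            cfg$stressFraction >= 0, cfg$stressFraction <= 0.5,
            cfg$samplingRate > 0, cfg$nSubjects >= 2L)
  class(cfg) <- "CohortConfig"
  cfg
}

# Nominal (valence, arousal) SAM targets of the four emotional conditions.
samTargets <- function() {
  list(pos_excited = c(8L, 8L), pos_calm = c(8L, 2L),
       neg_excited = c(2L, 8L), neg_calm = c(2L, 2L))
}

# Directed coupling specification for one subject-condition.
#
# Base dynamics: each channel an AR(2) with a1 = 0.5, a2 = -0.2.  Directed
# edges act at lag 4 (16 ms at 250 Hz, a realistic inter-regional delay) and
# are arranged front -> central -> parietal -> temporal (a DAG, so any gain
# leaves the model stable):
#   arousal:  F3->C3, F4->C4 gain 0.40 (excited) vs 0.05 (calm)
#   valence:  C3->P3 strong / C4->P4 weak when positive, flipped when negative
#   backbone: P3->T7, P4->T8 at 0.15
# A backward edge P3 -> C3 with gain 0.30 is present in every condition
# (resting included); stress adds 0.30 * effectSize to it, so stress
# perturbs the left-parietal outflow without confounding the emotion edges
# (the baseline is common to all conditions).
conditionSpec <- function(condition, stressed, effectSize, channels,
                          samplingRate, gainJitter = NULL) {
  nc <- length(channels)
  idx <- function(nm) match(nm, channels)
  A <- list(diag(0.5, nc), diag(-0.2, nc), matrix(0, nc, nc), matrix(0, nc, nc))
  jit <- function(g) if (is.null(gainJitter)) g else g * gainJitter
  edge <- function(from, to, g, lag = 4L)
    A[[lag]][idx(to), idx(from)] <<- A[[lag]][idx(to), idx(from)] + jit(g)
  edge("P3", "T7", 0.15); edge("P4", "T8", 0.15)
  stressGain <- if (stressed) 0.30 * effectSize else 0
  edge("P3", "C3", 0.30 + stressGain)
  if (condition != "resting") {
    sam <- samTargets()[[condition]]
    hiAr <- sam[2] >= 5
    edge("F3", "C3", if (hiAr) 0.40 else 0.05)
    edge("F4", "C4", if (hiAr) 0.40 else 0.05)
    pos <- sam[1] >= 5
    edge("C3", "P3", if (pos) 0.40 else 0.05)
    edge("C4", "P4", if (pos) 0.05 else 0.40)
  }
  MVARModel(A, noiseCov = diag(nc), channelNames = channels,
            samplingRate = samplingRate)
}

# Draw PSS totals: round(nStr * ...) subjects from the upper tail, as many
# from the lower tail, the rest from the middle of N(pssMean, pssSd),
# rounded and clipped to [0, 56].  Margins of ~1 SD/2 around the nominal
# cuts keep the empirical mu +/- sigma/2 rule consistent with the draw.
drawPss <- function(n, fraction, mean, sd) {
  nStr <- round(n * fraction)
  nFree <- round(n * fraction)
  nMid <- n - nStr - nFree
  lowCut <- mean - sd / 2; highCut <- mean + sd / 2
  margin <- 0.4 * sd
  rtrunc <- function(k, lo, hi) {
    out <- numeric(0)
    while (length(out) < k) {
      x <- stats::rnorm(2 * k + 10, mean, sd)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(k)]
  }
  scores <- c(rtrunc(nStr, highCut + margin, 56),
              rtrunc(nMid, lowCut + margin, highCut - margin),
              rtrunc(nFree, 0, lowCut - margin))
  pmin(56L, pmax(0L, as.integer(round(scores))))
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject PSS totals, assigns stress groups by the sample
#' mu +/- sigma/2 rule, and simulates per-condition EEG from
#' condition-specific directed-coupling specifications (stressed subjects'
#' specs perturbed by `effectSize`), plus a resting-state recording.  SAM
#' responses are the condition's nominal (valence, arousal) target plus an
#' integer jitter of at most `samNoise`, clipped to [1, 9].
#'
#' @param config a [cohortConfig()] list (defaults used when omitted).
#' @return A list of [SubjectRecord-class] objects with the config attached
#'   as attribute `config`.
#' @examples
#' cohort <- generateCohort(cohortConfig(nSubjects = 4, segmentDuration = 4,
#'                                       restingDuration = 4))
#' cohort[[1]]
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$nSubjects
  conds <- names(samTargets())[seq_len(config$nConditions)]
  pss <- drawPss(n, config$stressFraction, config$pssMean, config$pssSd)
  grouping <- stressGroup(pss)
  nSeg <- round(config$segmentDuration * config$samplingRate)
  nRest <- round(config$restingDuration * config$samplingRate)
  nc <- length(config$channels)
  cohort <- vector("list", n)
  for (s in seq_len(n)) {
    stressed <- grouping$group[s] == "stressed"
    jitter <- exp(stats::rnorm(1, 0, 0.1))
    sigs <- list(); sam <- list()
    for (cond in conds) {
      spec <- conditionSpec(cond, stressed, config$effectSize,
                            config$channels, config$samplingRate,
                            gainJitter = jitter)
      if (spectralRadius(spec) >= 1)
        stop("effectSize produces a non-stationary coupling spec")
      sigs[[cond]] <- simulateMVAR(spec, nSeg)
      tgt <- samTargets()[[cond]]
      jit <- sample(-config$samNoise:config$samNoise, 2L, replace = TRUE)
      sam[[cond]] <- pmin(9L, pmax(1L, tgt + jit))
    }
    restSpec <- conditionSpec("resting", stressed, config$effectSize,
                              config$channels, config$samplingRate,
                              gainJitter = jitter)
    if (spectralRadius(restSpec) >= 1)
      stop("effectSize produces a non-stationary coupling spec")
    rest <- simulateMVAR(restSpec, nRest)
    cohort[[s]] <- new("SubjectRecord",
                       subjectId = sprintf("S%02d", s),
                       pssScore = pss[s],
                       stressGroup = grouping$group[s],
                       signals = sigs, sam = sam, restingSignal = rest)
  }
  names(cohort) <- vapply(cohort, function(x) x@subjectId, character(1))
  attr(cohort, "config") <- config
  cohort
}
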