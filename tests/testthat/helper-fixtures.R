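# Shared fixtures: all built in code at test time.

whiteSignal <- function(n = 2000, nc = 2, fs = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  EEGSignal(matrix(rnorm(n * nc), n, nc), fs)
}

toneSignal <- function(freq, n = 2500, fs = 250, nc = 1) {
  t <- (seq_len(n) - 1) / fs
  EEGSignal(matrix(rep(sin(2 * pi * freq * t), nc), n, nc), fs)
}

# 2-channel unidirectional coupling 1 -> 2 at the given lag.
unidirSpec <- function(gain = 0.4, lag = 2L, a1 = 0.5) {
  A <- replicate(lag, matrix(0, 2, 2), simplify = FALSE)
  A[[1]] <- A[[1]] + diag(a1, 2)
  A[[lag]][2, 1] <- gain
  MVARModel(A)
}

# Small, fast cohort for end-to-end plumbing tests.
tinyCohort <- function(seed = 7, nSubjects = 4, segmentDuration = 6,
                       restingDuration = 6, ...) {
  generateCohort(cohortConfig(nSubjects = nSubjects,
                              segmentDuration = segmentDuration,
                              restingDuration = restingDuration,
                              seed = seed, ...))
}

# Nominal SAM targets restated independently of the generator internals.
samTargets_fixture <- function() {
  list(pos_excited = c(8L, 8L), pos_calm = c(8L, 2L),
       neg_excited = c(2L, 8L), neg_calm = c(2L, 2L))
}

# 8-channel spec with one F3 -> C3 edge at lag 4, for featurize tests.
conditionSpecFixture <- function() {
  channels <- c("F3", "F4", "C3", "C4", "P3", "P4", "T7", "T8")
  A <- list(diag(0.5, 8), diag(-0.2, 8), matrix(0, 8, 8), matrix(0, 8, 8))
  A[[4]][3, 1] <- 0.4
  MVARModel(A, channelNames = channels)
}
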