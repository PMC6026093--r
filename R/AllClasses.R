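#' @import methods
NULL

#' Multichannel EEG signal
#'
#' An S4 container for a samples-by-channels real matrix together with its
#' sampling rate and channel names.  All preprocessing and connectivity
#' estimators in the package consume and return this class.
#'
#' @slot data numeric matrix, samples x channels; no missing values.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames character vector, one name per column of `data`.
#' @slot isNormalized logical; `TRUE` after [normalizeAmplitude()] has mapped
#'   every channel to the unit interval.
#'
#' @seealso [EEGSignal()] for the user-facing constructor.
#' @export
setClass("EEGSignal",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channelNames = "character",
    isNormalized = "logical"
  ),
  prototype(isNormalized = FALSE)
)

setValidity("EEGSignal", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (anyNA(object@data))
    msg <- c(msg, "data contains missing values")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@channelNames) != ncol(object@data))
    msg <- c(msg, sprintf("channelNames length (%d) != number of channels (%d)",
                          length(object@channelNames), ncol(object@data)))
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGSignal
#'
#' @param data numeric matrix (samples x channels) or data.frame.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames channel names; defaults to `colnames(data)` or
#'   `ch1 ... chK`.
#' @param isNormalized logical flag, set by [normalizeAmplitude()].
#' @return An [EEGSignal-class] object.
#' @examples
#' sig <- EEGSignal(matrix(rnorm(500 * 2), 500, 2), samplingRate = 250)
#' nSamples(sig)
#' @export
EEGSignal <- function(data, samplingRate, channelNames = NULL,
                      isNormalized = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channelNames)) {
    channelNames <- colnames(data)
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(ncol(data)))
  }
  colnames(data) <- channelNames
  new("EEGSignal", data = data, samplingRate = as.numeric(samplingRate),
      channelNames = as.character(channelNames),
      isNormalized = isNormalized)
}

#' Multivariate autoregressive model
#'
#' Coefficient matrices `A[[r]]` (r = 1..order), innovation covariance and
#' metadata of a fitted or specified MVAR process
#' `w_n = sum_r A^r w_{n-r} + xi_n`.
#'
#' @slot order model order (number of lags).
#' @slot A list of channels x channels coefficient matrices, one per lag.
#' @slot noiseCov innovation covariance matrix (symmetric positive definite).
#' @slot channelNames character vector of channel names.
#' @slot samplingRate sampling rate in Hz of the modelled signal.
#' @export
setClass("MVARModel",
  representation(
    order = "integer",
    A = "list",
    noiseCov = "matrix",
    channelNames = "character",
    samplingRate = "numeric"
  )
)

setValidity("MVARModel", function(object) {
  msg <- character()
  nc <- length(object@channelNames)
  if (object@order < 1L) msg <- c(msg, "order must be >= 1")
  if (length(object@A) != object@order)
    msg <- c(msg, "length(A) must equal order")
  for (r in seq_along(object@A)) {
    if (!is.matrix(object@A[[r]]) || any(dim(object@A[[r]]) != nc))
      msg <- c(msg, sprintf("A[[%d]] must be a %dx%d matrix", r, nc, nc))
  }
  if (any(dim(object@noiseCov) != nc))
    msg <- c(msg, "noiseCov dimensions must match channel count")
  else {
    if (max(abs(object@noiseCov - t(object@noiseCov))) > 1e-8)
      msg <- c(msg, "noiseCov must be symmetric")
    if (any(diag(object@noiseCov) <= 0))
      msg <- c(msg, "noiseCov must have positive diagonal")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an MVAR model specification
#'
#' Used both for fitted models and for generative coupling specifications fed
#' to [simulateMVAR()].
#'
#' @param A list of channels x channels lag-coefficient matrices (lag 1 first).
#' @param noiseCov innovation covariance; defaults to the identity.
#' @param channelNames channel names; default `ch1 ... chK`.
#' @param samplingRate sampling rate in Hz (default 250).
#' @return An [MVARModel-class] object.
#' @examples
#' m <- MVARModel(list(matrix(c(.5, .4, 0, .5), 2, 2)))
#' spectralRadius(m)
#' @export
MVARModel <- function(A, noiseCov = NULL, channelNames = NULL,
                      samplingRate = 250) {
  if (is.matrix(A)) A <- list(A)
  nc <- nrow(A[[1]])
  if (is.null(noiseCov)) noiseCov <- diag(nc)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nc))
  A <- lapply(A, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(channelNames, channelNames)
    m
  })
  new("MVARModel", order = length(A), A = A,
      noiseCov = as.matrix(noiseCov),
      channelNames = as.character(channelNames),
      samplingRate = as.numeric(samplingRate))
}

#' Frequency-resolved directed connectivity tensor
#'
#' Channels x channels x frequencies array of non-negative connectivity
#' values.  The orientation contract is fixed: entry `[i, j, f]` quantifies
#' the flow from channel `j` (source) into channel `i` (sink) at frequency
#' `freqs[f]`.
#'
#' @slot values numeric array, channels x channels x frequencies.
#' @slot method one of `"dtf"`, `"gpdc"`, `"psi"`.
#' @slot freqs frequency grid in Hz.
#' @slot channelNames channel names.
#' @export
setClass("ConnectivityTensor",
  representation(
    values = "array",
    method = "character",
    freqs = "numeric",
    channelNames = "character"
  )
)

setValidity("ConnectivityTensor", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-d array")
  else {
    if (d[1] != d[2]) msg <- c(msg, "first two dimensions must match")
    if (d[3] != length(object@freqs))
      msg <- c(msg, "third dimension must match freqs")
    if (d[1] != length(object@channelNames))
      msg <- c(msg, "channelNames must match channel dimension")
  }
  if (!object@method %in% c("dtf", "gpdc", "psi"))
    msg <- c(msg, "method must be one of dtf, gpdc, psi")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-band phase slope index estimate
#'
#' Raw and jackknife-normalized PSI matrices for one frequency band, together
#' with the per-entry standard deviation estimate and the Welch segmentation
#' used.  `psi[i, j] > 0` indicates information flow i -> j; both matrices
#' are exactly antisymmetric with zero diagonal.
#'
#' @slot psi raw PSI matrix (channels x channels).
#' @slot psiNorm jackknife-normalized PSI matrix.
#' @slot std jackknife standard deviation per entry (symmetric, >= 0).
#' @slot band numeric length-2 vector, band limits in Hz.
#' @slot segmentCount number of Welch segments k1 used.
#' @slot deltaF frequency resolution (bin spacing) in Hz.
#' @slot channelNames channel names.
#' @export
setClass("PsiEstimate",
  representation(
    psi = "matrix",
    psiNorm = "matrix",
    std = "matrix",
    band = "numeric",
    segmentCount = "integer",
    deltaF = "numeric",
    channelNames = "character"
  )
)

setValidity("PsiEstimate", function(object) {
  msg <- character()
  if (max(abs(object@psi + t(object@psi))) > 1e-12 * max(1, max(abs(object@psi))))
    msg <- c(msg, "psi must be antisymmetric")
  if (any(diag(object@psi) != 0)) msg <- c(msg, "psi diagonal must be zero")
  if (any(object@std < 0)) msg <- c(msg, "std must be non-negative")
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    msg <- c(msg, "band must be (low, high) with low < high")
  if (length(msg)) msg else TRUE
})

#' Per-subject record of a cohort
#'
#' Everything the pipeline needs about one subject: per-condition EEG
#' segments and SAM self-reports, a resting-state recording, the PSS total
#' and the stress-group assignment.
#'
#' @slot subjectId subject identifier.
#' @slot pssScore integer perceived-stress total in [0, 56].
#' @slot stressGroup one of `"stressed"`, `"stress_free"`, `"middle"`.
#' @slot signals named list of [EEGSignal-class], one per emotional condition.
#' @slot sam named list of `c(valence, arousal)` integer pairs in [1, 9].
#' @slot restingSignal resting-state (eyes-closed) [EEGSignal-class].
#' @export
setClass("SubjectRecord",
  representation(
    subjectId = "character",
    pssScore = "integer",
    stressGroup = "character",
    signals = "list",
    sam = "list",
    restingSignal = "EEGSignal"
  )
)

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (object@pssScore < 0L || object@pssScore > 56L)
    msg <- c(msg, "pssScore must be in [0, 56]")
  if (!object@stressGroup %in% c("stressed", "stress_free", "middle"))
    msg <- c(msg, "stressGroup must be stressed/stress_free/middle")
  if (!setequal(names(object@signals), names(object@sam)))
    msg <- c(msg, "signals and sam must cover the same conditions")
  for (cond in names(object@sam)) {
    v <- object@sam[[cond]]
    if (length(v) != 2L || any(v < 1) || any(v > 9))
      msg <- c(msg, sprintf("sam[[%s]] must be (valence, arousal) in [1,9]", cond))
  }
  if (length(msg)) msg else TRUE
})

#' Welch cross-spectral estimate
#'
#' One- or multi-channel spectral estimate: `values[i, j, f]` is the
#' cross-spectral density between channels i and j at `freqs[f]`.  When the
#' estimate comes from Welch segmentation the per-segment Fourier
#' coefficients are retained in `segmentFFT` so that leave-one-segment-out
#' (jackknife) statistics can be formed without recomputation.
#'
#' @slot freqs frequency grid in Hz (ascending, within [0, Nyquist]).
#' @slot values complex array, channels x channels x frequencies, Hermitian
#'   in its first two dimensions.
#' @slot estimator one of `"periodogram"`, `"wiener_khinchin"`,
#'   `"welch_hanning"`.
#' @slot segmentCount number of averaged segments (k1; 1 for single-window
#'   estimators).
#' @slot segmentLength segment length in samples.
#' @slot segmentFFT complex array channels x frequencies x segments (may have
#'   zero extent when not applicable).
#' @slot channelNames channel names.
#' @export
setClass("SpectralEstimate",
  representation(
    freqs = "numeric",
    values = "array",
    estimator = "character",
    segmentCount = "integer",
    segmentLength = "integer",
    segmentFFT = "array",
    channelNames = "character"
  )
)

setValidity("SpectralEstimate", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != d[2] || d[3] != length(object@freqs))
    msg <- c(msg, "values must be channels x channels x freqs")
  if (is.unsorted(object@freqs))
    msg <- c(msg, "freqs must be ascending")
  if (!object@estimator %in% c("periodogram", "wiener_khinchin", "welch_hanning"))
    msg <- c(msg, "unknown estimator tag")
  if (length(msg)) msg else TRUE
})
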