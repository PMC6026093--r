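#' Standard 4 Hz filter-bank band definitions
#'
#' The seven contiguous 4 Hz bands covering 4-32 Hz used throughout the
#' connectivity feature extraction:
#' [4-8], [8-12], [12-16], [16-20], [20-24], [24-28], [28-32] Hz.
#'
#' @return A data.frame with columns `low`, `high` (Hz) and `label`.
#' @examples
#' standardBands()
#' @export
standardBands <- function() {
  low <- seq(4, 28, by = 4)
  data.frame(low = low, high = low + 4,
             label = sprintf("[%d-%d]", low, low + 4),
             stringsAsFactors = FALSE)
}

#' Rescale each channel to the unit interval
#'
#' Per channel affine map x -> (x - min) / (max - min).  Removes
#' between-recording amplitude differences; directed connectivity estimates
#' are invariant to this scaling (each estimator normalizes amplitude away).
#'
#' @param signal an [EEGSignal-class].
#' @return The signal with every channel in [0, 1] and `isNormalized` set.
#' @export
normalizeAmplitude <- function(signal) {
  stopifnot(is(signal, "EEGSignal"))
  x <- signalData(signal)
  rng <- apply(x, 2L, range)
  flat <- rng[2, ] - rng[1, ] == 0
  if (any(flat))
    stop("constant channel(s), cannot normalize: ",
         paste(channelNames(signal)[flat], collapse = ", "))
  x <- sweep(sweep(x, 2L, rng[1, ], "-"), 2L, rng[2, ] - rng[1, ], "/")
  EEGSignal(x, samplingRate(signal), channelNames(signal), isNormalized = TRUE)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the filter is phase-preserving -- a prerequisite for phase-based
#' connectivity (PSI) downstream.  Defaults to the broadband 4-32 Hz EEG
#' analysis range.
#'
#' @param sig an [EEGSignal-class].
#' @param low lower edge in Hz (default 4).
#' @param high upper edge in Hz (default 32).
#' @param order filter order (default 4).
#' @return Filtered [EEGSignal-class], same length and channels.
#' @export
bandpass <- function(sig, low = 4, high = 32, order = 4) {
  stopifnot(is(sig, "EEGSignal"))
  fs <- samplingRate(sig)
  nyq <- fs / 2
  if (!(0 < low && low < high && high <= nyq))
    stop(sprintf("invalid band [%g, %g] Hz for sampling rate %g Hz", low, high, fs))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x <- signalData(sig)
  y <- apply(x, 2L, function(ch) signal::filtfilt(bf, ch))
  EEGSignal(y, fs, channelNames(sig), isNormalized = FALSE)
}

#' Decompose a signal into the seven 4 Hz analysis bands
#'
#' Applies [bandpass()] once per band of [standardBands()].  The returned
#' list carries one filtered [EEGSignal-class] per band, named by band label,
#' with the band limits attached as the `band` attribute.
#'
#' @param sig an [EEGSignal-class] (raw or already broadband-filtered).
#' @param order filter order per branch (default 4).
#' @return Named list of 7 [EEGSignal-class] objects in ascending band order.
#' @export
filterBank <- function(sig, order = 4) {
  bands <- standardBands()
  out <- vector("list", nrow(bands))
  names(out) <- bands$label
  for (b in seq_len(nrow(bands))) {
    branch <- bandpass(sig, bands$low[b], bands$high[b], order = order)
    attr(branch, "band") <- c(bands$low[b], bands$high[b])
    out[[b]] <- branch
  }
  out
}

#' Extract a rectangular analysis window
#'
#' Returns samples `start ... start + length - 1` of every channel under the
#' 0-based, half-open convention `[start, start + length)`; no taper is
#' applied.  With the defaults (start 500, length 512) at 250 Hz the window
#' covers 2.048 s beginning at t = 2 s.
#'
#' @param sig an [EEGSignal-class].
#' @param start 0-based start sample (default 500).
#' @param length window length in samples (default 512).
#' @return [EEGSignal-class] holding the windowed segment; window position
#'   recorded in attributes `windowStart` / `windowLength`.
#' @export
extractWindow <- function(sig, start = 500L, length = 512L) {
  stopifnot(is(sig, "EEGSignal"))
  start <- as.integer(start); length <- as.integer(length)
  n <- nSamples(sig)
  if (length <= 0L) stop("window length must be positive")
  if (start < 0L || start + length > n)
    stop(sprintf("window [%d, %d) out of range; available samples [0, %d)",
                 start, start + length, n))
  w <- EEGSignal(signalData(sig)[start + seq_len(length), , drop = FALSE],
                 samplingRate(sig), channelNames(sig),
                 isNormalized = sig@isNormalized)
  attr(w, "windowStart") <- start
  attr(w, "windowLength") <- length
  w
}
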