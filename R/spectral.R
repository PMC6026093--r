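#' Lagged auto-/cross-correlation of windowed segments
#'
#' `crossCorrelation(wi, wj)[l + 1]` estimates `E[wi_n wj_{n+l}]` for lags
#' l = 0 ... maxLag.  Two normalizations are exposed: `"unbiased"` divides the
#' lag-l sum by (N - l) and is the default for the correlation accessor;
#' `"biased"` divides by N and is the form under which the periodogram
#' identity with the cross-spectral density is exact.
#'
#' @param wi,wj numeric vectors of equal length (one channel of a windowed
#'   segment).
#' @param maxLag largest lag; default N - 1.
#' @param normalization `"unbiased"` (1/(N-l)) or `"biased"` (1/N).
#' @return Numeric vector of length `maxLag + 1`, lags 0 ... maxLag.
#' @examples
#' autoCorrelation(c(1, -1, 1, -1), maxLag = 1)  # c(1, -1)
#' @export
crossCorrelation <- function(wi, wj, maxLag = length(wi) - 1L,
                             normalization = c("unbiased", "biased")) {
  normalization <- match.arg(normalization)
  n <- length(wi)
  if (n == 0L) stop("empty segment")
  if (length(wj) != n) stop("segment length mismatch")
  if (maxLag >= n) stop("maxLag must be < segment length")
  r <- vapply(0:maxLag, function(l) {
    s <- sum(wi[seq_len(n - l)] * wj[seq_len(n - l) + l])
    s / if (normalization == "unbiased") (n - l) else n
  }, numeric(1))
  r
}

#' @rdname crossCorrelation
#' @param w numeric vector.
#' @export
autoCorrelation <- function(w, maxLag = length(w) - 1L,
                            normalization = c("unbiased", "biased")) {
  crossCorrelation(w, w, maxLag = maxLag, normalization = match.arg(normalization))
}

#' Discrete Fourier transform of a windowed segment
#'
#' Forward DFT `z_f = sum_n w_n exp(-i 2 pi f n / N)` (the `stats::fft`
#' convention).  Satisfies Parseval's identity
#' `sum |w|^2 = (1/N) sum |z|^2`.
#'
#' @param w numeric or complex vector.
#' @return Complex vector of the same length.
#' @export
dftTransform <- function(w) {
  if (length(w) == 0L) stop("empty input")
  stats::fft(w)
}

#' One-sided frequency grid for an N-point DFT
#'
#' `f_k = k Fs / N` for k = 0 ... floor(N/2).
#'
#' @param n segment length in samples.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of frequencies in Hz.
#' @export
fftFreqs <- function(n, fs) (0:(n %/% 2)) * fs / n

#' Single-window (cross-) power spectral density
#'
#' Two estimators of the channels x channels cross-spectral matrix of one
#' rectangular window, on the one-sided grid [fftFreqs()]:
#' \describe{
#'   \item{periodogram}{`S_ij(f) = (1/N) z_i(f) conj(z_j(f))` from the DFT of
#'     the raw samples.}
#'   \item{wiener_khinchin}{the DFT of the lagged cross-correlation sequence
#'     (both lag signs, circularly folded onto 0 ... N-1).  Under the biased
#'     (1/N) correlation normalization this equals the periodogram to
#'     machine precision; the unbiased variant is provided for inspection
#'     and does not satisfy the identity.}
#' }
#'
#' @param sig an [EEGSignal-class] (typically a windowed segment).
#' @param estimator `"periodogram"` or `"wiener_khinchin"`.
#' @param normalization correlation normalization for the Wiener-Khinchin
#'   route; `"biased"` (default) or `"unbiased"`.
#' @return A [SpectralEstimate-class].
#' @export
spectralDensity <- function(sig, estimator = c("periodogram", "wiener_khinchin"),
                            normalization = c("biased", "unbiased")) {
  stopifnot(is(sig, "EEGSignal"))
  estimator <- match.arg(estimator)
  normalization <- match.arg(normalization)
  x <- signalData(sig)
  n <- nrow(x); nc <- ncol(x)
  keep <- seq_len(n %/% 2 + 1L)
  freqs <- fftFreqs(n, samplingRate(sig))
  vals <- array(0i, dim = c(nc, nc, length(keep)))
  if (estimator == "periodogram") {
    z <- stats::mvfft(x)
    for (i in seq_len(nc))
      for (j in seq_len(nc))
        vals[i, j, ] <- (z[, i] * Conj(z[, j]))[keep] / n
  } else {
    for (i in seq_len(nc))
      for (j in seq_len(nc)) {
        # fold positive lags of r_{ji} with negative lags (= r_{ij}[N-l])
        rji <- crossCorrelation(x[, j], x[, i], n - 1L, normalization)
        rij <- crossCorrelation(x[, i], x[, j], n - 1L, normalization)
        g <- rji
        if (n > 1L) g[2:n] <- g[2:n] + rij[n:2]
        vals[i, j, ] <- stats::fft(g)[keep]
      }
  }
  new("SpectralEstimate", freqs = freqs, values = vals,
      estimator = estimator, segmentCount = 1L, segmentLength = as.integer(n),
      segmentFFT = array(0i, dim = c(0L, 0L, 0L)),
      channelNames = channelNames(sig))
}

#' Welch cross-spectral density over Hanning-tapered segments
#'
#' Splits the recording into `k1 = floor(n / segLength)` disjoint segments,
#' tapers each with a Hanning window, and averages the per-segment
#' cross-spectra `S_ij(f) = (1/k1) sum_k z_ik(f) conj(z_jk(f))`.  The
#' per-segment Fourier coefficients are retained so leave-one-segment-out
#' jackknife estimates (PSI standardization) can be formed cheaply.
#'
#' @param sig an [EEGSignal-class].
#' @param segLength segment length L_T in samples (default 256).
#' @return A [SpectralEstimate-class] with `segmentCount >= 2`.
#' @export
welchCPSD <- function(sig, segLength = 256L) {
  stopifnot(is(sig, "EEGSignal"))
  x <- signalData(sig)
  n <- nrow(x); nc <- ncol(x)
  segLength <- as.integer(segLength)
  if (segLength < 4L) stop("segLength too small")
  k1 <- n %/% segLength
  if (k1 < 2L)
    stop(sprintf("need at least 2 segments (jackknife); n = %d gives k1 = %d at segLength %d",
                 n, k1, segLength))
  taper <- 0.5 * (1 - cos(2 * pi * (0:(segLength - 1L)) / (segLength - 1L)))
  keep <- seq_len(segLength %/% 2 + 1L)
  freqs <- fftFreqs(segLength, samplingRate(sig))
  segFFT <- array(0i, dim = c(nc, length(keep), k1))
  for (k in seq_len(k1)) {
    idx <- (k - 1L) * segLength + seq_len(segLength)
    seg <- x[idx, , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))   # constant detrend per segment
    z <- stats::mvfft(seg * taper)
    segFFT[, , k] <- t(z[keep, , drop = FALSE])
  }
  vals <- array(0i, dim = c(nc, nc, length(keep)))
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      vals[i, j, ] <- rowMeans(segFFT[i, , , drop = TRUE] *
                               Conj(segFFT[j, , , drop = TRUE]))
  new("SpectralEstimate", freqs = freqs, values = vals,
      estimator = "welch_hanning", segmentCount = as.integer(k1),
      segmentLength = segLength, segmentFFT = segFFT,
      channelNames = channelNames(sig))
}

#' Complex coherency from a cross-spectral estimate
#'
#' `c_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))`; magnitude bounded by 1,
#' unit diagonal, Hermitian.
#'
#' @param S a [SpectralEstimate-class].
#' @return Complex array channels x channels x frequencies.
#' @export
complexCoherency <- function(S) {
  stopifnot(is(S, "SpectralEstimate"))
  v <- S@values
  nc <- dim(v)[1]; nf <- dim(v)[3]
  p <- matrix(0, nc, nf)
  for (i in seq_len(nc)) p[i, ] <- Re(v[i, i, ])
  bad <- which(apply(p <= 0, 2L, any))
  if (length(bad))
    stop("zero (or negative) diagonal power at frequencies: ",
         paste(signif(S@freqs[bad], 4), collapse = ", "))
  coh <- array(0i, dim = dim(v))
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      coh[i, j, ] <- v[i, j, ] / sqrt(p[i, ] * p[j, ])
  coh
}
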