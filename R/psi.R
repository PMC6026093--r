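# Band bin selection: indices k of the frequency grid such that both f_k and
# f_k + deltaF lie inside [low, high].
psiBandBins <- function(freqs, band) {
  if (length(freqs) < 2L) stop("spectral grid too short")
  deltaF <- freqs[2] - freqs[1]
  idx <- which(freqs >= band[1] & (freqs + deltaF) <= band[2])
  idx <- idx[idx < length(freqs)]
  if (length(idx) < 2L)
    stop(sprintf("band [%g, %g] Hz spans < 2 usable bins at resolution %g Hz",
                 band[1], band[2], deltaF))
  idx
}

# Raw PSI matrix from a coherency array restricted to band bins.
# psi[i, j] = Im sum_{f in Fp} Conj(c_ij(f)) c_ij(f + deltaF); positive
# values indicate flow i -> j under the forward-DFT phase convention.
psiFromCoherency <- function(coh, bins) {
  nc <- dim(coh)[1]
  psi <- matrix(0, nc, nc)
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      psi[i, j] <- sum(Im(Conj(coh[i, j, bins]) * coh[i, j, bins + 1L]))
  (psi - t(psi)) / 2  # enforce exact antisymmetry against accumulated roundoff
}

#' Raw phase slope index for one band
#'
#' Estimates the Welch cross-spectrum over Hanning segments, forms the
#' complex coherency, and sums `Im(conj(c_ij(f)) c_ij(f + deltaF))` over the
#' band's frequency bins.  `psi[i, j] > 0` indicates information flow
#' i -> j (channel i temporally leads j).
#'
#' @param sig an [EEGSignal-class].
#' @param band numeric `(low, high)` in Hz (default the broadband 4-32).
#' @param segLength Welch segment length L_T in samples (default 256).
#' @return A [PsiEstimate-class] with the raw `psi` matrix; `psiNorm` and
#'   `std` are zero until [psiNormalized()] fills them.
#' @export
psiRaw <- function(sig, band = c(4, 32), segLength = 256L) {
  S <- welchCPSD(sig, segLength)
  bins <- psiBandBins(S@freqs, band)
  psi <- psiFromCoherency(complexCoherency(S), bins)
  nc <- nChannels(sig)
  new("PsiEstimate", psi = psi, psiNorm = matrix(0, nc, nc),
      std = matrix(0, nc, nc), band = as.numeric(band),
      segmentCount = S@segmentCount,
      deltaF = S@freqs[2] - S@freqs[1],
      channelNames = channelNames(sig))
}

# Jackknife over Welch segments: raw psi, per-entry std, normalized psi.
# segFFT: channels x freqs x segments array restricted later to band bins.
psiJackknife <- function(segFFT, freqs, band) {
  nc <- dim(segFFT)[1]
  k1 <- dim(segFFT)[3]
  bins <- psiBandBins(freqs, band)
  use <- sort(unique(c(bins, bins + 1L)))
  pos <- match(bins, use)
  Z <- segFFT[, use, , drop = FALSE]   # nc x nb x k1
  nb <- length(use)
  Tfull <- array(0i, dim = c(nc, nc, nb))
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      Tfull[i, j, ] <- rowSums(matrix(Z[i, , ] * Conj(Z[j, , ]), nb, k1))
  # full-sample psi
  Sfull <- Tfull / k1
  cohFull <- array(0i, dim = c(nc, nc, nb))
  pf <- matrix(0, nc, nb)
  for (i in seq_len(nc)) pf[i, ] <- Re(Sfull[i, i, ])
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      cohFull[i, j, ] <- Sfull[i, j, ] / sqrt(pf[i, ] * pf[j, ])
  psi <- matrix(0, nc, nc)
  for (i in seq_len(nc))
    for (j in seq_len(nc))
      psi[i, j] <- sum(Im(Conj(cohFull[i, j, pos]) * cohFull[i, j, pos + 1L]))
  psi <- (psi - t(psi)) / 2
  # leave-one-segment-out psi
  jk <- array(0, dim = c(nc, nc, k1))
  for (i in seq_len(nc - 1L))
    for (j in (i + 1L):nc) {
      Zi <- matrix(Z[i, , ], nb, k1); Zj <- matrix(Z[j, , ], nb, k1)
      Sij <- (Tfull[i, j, ] - Zi * Conj(Zj)) / (k1 - 1L)   # nb x k1
      Sii <- Re(Tfull[i, i, ] - Zi * Conj(Zi)) / (k1 - 1L)
      Sjj <- Re(Tfull[j, j, ] - Zj * Conj(Zj)) / (k1 - 1L)
      cij <- Sij / sqrt(Sii * Sjj)
      p <- colSums(Im(Conj(cij[pos, , drop = FALSE]) *
                      cij[pos + 1L, , drop = FALSE]))
      jk[i, j, ] <- p
      jk[j, i, ] <- -p
    }
  ctr <- sweep(jk, c(1, 2), apply(jk, c(1, 2), mean))
  std <- sqrt((k1 - 1) / k1 * apply(ctr^2, c(1, 2), function(v) sum(v)))
  std <- (std + t(std)) / 2
  psiN <- matrix(0, nc, nc)
  ok <- std > 0
  psiN[ok] <- psi[ok] / std[ok]
  if (any(!ok & row(std) != col(std)))
    warning("zero jackknife std for some channel pair(s); normalized PSI set to 0")
  list(psi = psi, std = std, psiNorm = (psiN - t(psiN)) / 2, k1 = k1)
}

#' Jackknife-normalized phase slope index for one band
#'
#' Standardizes the raw PSI by its leave-one-segment-out jackknife standard
#' deviation: `psiNorm = psi / std(psi)` with
#' `std = sqrt((k1-1)/k1 * sum_k (psi_(-k) - mean)^2)` over the k1 Welch
#' segments.  Under independence the normalized value is approximately
#' standard normal, so |psiNorm| > 2 flags significant directed flow.
#'
#' @inheritParams psiRaw
#' @return A [PsiEstimate-class] with `psi`, `std` and `psiNorm` filled.
#' @export
psiNormalized <- function(sig, band = c(4, 32), segLength = 256L) {
  S <- welchCPSD(sig, segLength)
  res <- psiJackknife(S@segmentFFT, S@freqs, band)
  new("PsiEstimate", psi = res$psi, psiNorm = res$psiNorm, std = res$std,
      band = as.numeric(band), segmentCount = res$k1,
      deltaF = S@freqs[2] - S@freqs[1],
      channelNames = channelNames(sig))
}

#' Per-band PSI feature vector
#'
#' Computes the (by default jackknife-normalized) PSI on each of the seven
#' 4 Hz bands, selecting each band's frequency bins from one broadband Welch
#' cross-spectrum, and flattens to a vector of length `7 x n_channels^2`
#' (band slowest, then the channels x channels PSI matrix with value
#' `psi[source, sink]`, named `band:source->sink`).
#'
#' @param sig an [EEGSignal-class].
#' @param segLength Welch segment length in samples (default 256).
#' @param normalized use the jackknife-normalized PSI (default) or the raw
#'   value.
#' @return Named numeric vector with attribute `indexMap`.
#' @export
psiFeaturize <- function(sig, segLength = 256L, normalized = TRUE) {
  S <- welchCPSD(sig, segLength)
  bands <- standardBands()
  nc <- nChannels(sig)
  cn <- channelNames(sig)
  out <- numeric(0); map <- NULL
  for (b in seq_len(nrow(bands))) {
    res <- psiJackknife(S@segmentFFT, S@freqs, c(bands$low[b], bands$high[b]))
    m <- if (normalized) res$psiNorm else res$psi
    v <- as.vector(m)    # column-major: source varies fastest within sink column
    names(v) <- sprintf("%s:%s->%s", bands$label[b],
                        rep(cn, times = nc), rep(cn, each = nc))
    out <- c(out, v)
    map <- rbind(map, data.frame(band = bands$label[b],
                                 source = rep(cn, times = nc),
                                 sink = rep(cn, each = nc),
                                 stringsAsFactors = FALSE))
  }
  attr(out, "indexMap") <- map
  attr(out, "method") <- "psi"
  out
}

#' Per-channel PSI flux map
#'
#' Splits the first `duration` seconds into disjoint windows of `window`
#' seconds, computes the raw broadband PSI matrix in each, and accumulates
#' per channel the net outflow `sum_windows sum_j psi[i, j]`.  Positive flux
#' marks a channel that predominantly sends information.
#'
#' @param sig an [EEGSignal-class] at least `duration` seconds long.
#' @param window window length in seconds (default 2).
#' @param duration total analysed duration in seconds (default 50).
#' @param band frequency band in Hz (default 4-32).
#' @param segLength Welch segment length within each window; the default
#'   (window/8, i.e. 8 segments of ~0.25 s) trades frequency resolution
#'   (~4 Hz, the filter-bank bandwidth) for enough segment averaging to
#'   stabilize the short-window coherency.
#' @return Named numeric vector (one flux value per channel) with attributes
#'   `nWindows`, `window`, `duration`.
#' @export
fluxMap <- function(sig, window = 2, duration = 50, band = c(4, 32),
                    segLength = NULL) {
  fs <- samplingRate(sig)
  nWin <- floor(duration / window)
  winN <- round(window * fs)
  if (nSamples(sig) < nWin * winN)
    stop(sprintf("signal too short: need %g s, have %.3f s",
                 duration, nSamples(sig) / fs))
  if (is.null(segLength)) segLength <- winN %/% 8L
  flux <- setNames(numeric(nChannels(sig)), channelNames(sig))
  for (w in seq_len(nWin)) {
    seg <- extractWindow(sig, (w - 1L) * winN, winN)
    est <- psiRaw(seg, band = band, segLength = segLength)
    flux <- flux + rowSums(est@psi)
  }
  attr(flux, "nWindows") <- nWin
  attr(flux, "window") <- window
  attr(flux, "duration") <- duration
  flux
}
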