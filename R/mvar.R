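# Unbiased lagged covariance R(l) = E[w_n w_{n-l}'] of a demeaned matrix.
laggedCov <- function(x, l) {
  n <- nrow(x)
  if (l == 0L) return(crossprod(x) / (n - 1L))
  crossprod(x[(l + 1L):n, , drop = FALSE], x[seq_len(n - l), , drop = FALSE]) / (n - l)
}

#' Fit an MVAR model by Yule-Walker
#'
#' Solves the multivariate Yule-Walker system
#' `sum_r A^r R(i - r) = R(i)`, i = 1..m, built from unbiased lagged
#' covariance estimates (block-Toeplitz least squares), then estimates the
#' innovation covariance from the model residuals.
#'
#' @param sig an [EEGSignal-class] (windowed segment or full recording).
#' @param order model order m (>= 1).
#' @return An [MVARModel-class]; residuals retained in attribute
#'   `residuals`.
#' @export
fitMVAR <- function(sig, order = 7L) {
  stopifnot(is(sig, "EEGSignal"))
  order <- as.integer(order)
  if (order <= 0L) stop("order must be positive")
  x <- signalData(sig)
  n <- nrow(x); nc <- ncol(x)
  if (n <= order * nc) stop("too few samples for the requested order")
  x <- sweep(x, 2L, colMeans(x))
  R <- lapply(0:order, function(l) laggedCov(x, l))
  # G[(block r), (block i)] = R(i - r); B [A^1 ... A^m] solves B G = C
  G <- matrix(0, nc * order, nc * order)
  for (r in seq_len(order))
    for (i in seq_len(order)) {
      d <- i - r
      blk <- if (d >= 0) R[[d + 1L]] else t(R[[-d + 1L]])
      G[(r - 1L) * nc + seq_len(nc), (i - 1L) * nc + seq_len(nc)] <- blk
    }
  C <- do.call(cbind, R[-1L])
  B <- tryCatch(t(solve(t(G), t(C))),
                error = function(e)
                  stop("singular lagged-covariance block (duplicated channels?)"))
  A <- lapply(seq_len(order), function(r) B[, (r - 1L) * nc + seq_len(nc), drop = FALSE])
  # residuals and innovation covariance
  pred <- matrix(0, n - order, nc)
  for (r in seq_len(order))
    pred <- pred + x[(order - r + 1L):(n - r), , drop = FALSE] %*% t(A[[r]])
  resid <- x[(order + 1L):n, , drop = FALSE] - pred
  Sigma <- crossprod(resid) / (nrow(resid) - 1L)
  Sigma <- (Sigma + t(Sigma)) / 2
  model <- MVARModel(A, noiseCov = Sigma, channelNames = channelNames(sig),
                     samplingRate = samplingRate(sig))
  attr(model, "residuals") <- resid
  model
}

#' Select the MVAR order by information criterion
#'
#' Fits orders 1 ... `maxOrder` and returns the order minimizing AIC
#' (`log det Sigma + 2 m nc^2 / N`); per-order criterion values are attached
#' as attribute `criterion`.
#'
#' @param sig an [EEGSignal-class].
#' @param maxOrder largest order to consider.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @return Selected order (integer) with attribute `criterion`.
#' @export
selectOrder <- function(sig, maxOrder = 10L, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  maxOrder <- as.integer(maxOrder)
  stopifnot(maxOrder >= 1L)
  n <- nSamples(sig); nc <- nChannels(sig)
  vals <- vapply(seq_len(maxOrder), function(m) {
    fit <- fitMVAR(sig, m)
    pen <- if (criterion == "aic") 2 else log(n)
    determinant(fit@noiseCov, logarithm = TRUE)$modulus + pen * m * nc^2 / n
  }, numeric(1))
  out <- which.min(vals)
  attr(out, "criterion") <- vals
  out
}

# A_bar(f) = I - sum_r A^r exp(-i 2 pi f r / Fs), all freqs at once.
abarSpectrum <- function(model, freqs) {
  nc <- nChannels(model)
  nf <- length(freqs)
  ab <- array(0i, dim = c(nc, nc, nf))
  I <- diag(nc)
  for (k in seq_len(nf)) {
    acc <- I
    for (r in seq_len(model@order))
      acc <- acc - model@A[[r]] * exp(-2i * pi * freqs[k] * r / samplingRate(model))
    ab[, , k] <- acc
  }
  ab
}

#' Spectral transfer function of an MVAR model
#'
#' `H(f) = Abar(f)^{-1}` with `Abar(f) = I - sum_r A^r e^{-i2pi f r / Fs}`.
#' The coefficient spectrum `Abar` is attached as attribute `Abar`.
#'
#' @param model an [MVARModel-class].
#' @param freqs frequencies in Hz (default 1 Hz grid over 4-32).
#' @return Complex array channels x channels x frequencies.
#' @export
transferFunction <- function(model, freqs = 4:32) {
  stopifnot(is(model, "MVARModel"))
  nyq <- samplingRate(model) / 2
  if (any(freqs < 0 | freqs > nyq)) stop("freqs must lie within [0, Nyquist]")
  ab <- abarSpectrum(model, freqs)
  H <- array(0i, dim = dim(ab))
  for (k in seq_along(freqs)) {
    H[, , k] <- tryCatch(solve(ab[, , k]),
                         error = function(e)
                           stop(sprintf("transfer function singular at %g Hz (near-unit-root model)",
                                        freqs[k])))
  }
  attr(H, "Abar") <- ab
  H
}

#' Normalized directed transfer function
#'
#' `gamma^2_{j->i}(f) = |H_ij(f)|^2 / sum_j' |H_ij'(f)|^2`: the causal
#' influence of source j on sink i, normalized over all sources feeding the
#' sink, so the tensor rows sum to 1 at every frequency.  Tensor entry
#' `[i, j, f]` holds the squared normalized DTF for flow j -> i.
#'
#' @param model an [MVARModel-class].
#' @param freqs frequency grid in Hz (default 1 Hz over 4-32).
#' @return A [ConnectivityTensor-class] with method `"dtf"`.
#' @export
dtf <- function(model, freqs = 4:32) {
  H <- transferFunction(model, freqs)
  h2 <- Mod(H)^2
  for (k in seq_along(freqs))
    h2[, , k] <- h2[, , k] / rowSums(h2[, , k])
  new("ConnectivityTensor", values = h2, method = "dtf",
      freqs = as.numeric(freqs), channelNames = channelNames(model))
}

#' (Generalized) partial directed coherence
#'
#' Plain PDC (default): `|pi_{j->i}(f)| = |Abar_ij(f)| /
#' sqrt(sum_i' |Abar_i'j(f)|^2)`, normalized over the sinks fed by source j,
#' so the squared tensor columns sum to 1 at every frequency.  With
#' `generalized = TRUE` each `Abar_ij` is weighted by the inverse innovation
#' standard deviation `1/sqrt(sigma_ii)` (the GPDC variant, invariant to
#' per-channel amplitude scale).  Tensor entry `[i, j, f]` holds
#' `|pi_{j->i}(f)|`.
#'
#' @param model an [MVARModel-class].
#' @param freqs frequency grid in Hz (default 1 Hz over 4-32).
#' @param generalized weight by innovation variances (default `FALSE`, the
#'   printed plain-PDC form).
#' @return A [ConnectivityTensor-class] with method `"gpdc"`.
#' @export
gpdc <- function(model, freqs = 4:32, generalized = FALSE) {
  stopifnot(is(model, "MVARModel"))
  ab <- abarSpectrum(model, freqs)
  w <- if (generalized) 1 / sqrt(diag(model@noiseCov)) else rep(1, nChannels(model))
  a2 <- Mod(ab * w)^2   # w recycles down rows i: weight 1/sigma_ii on row i
  vals <- array(0, dim = dim(a2))
  for (k in seq_along(freqs)) {
    cs <- colSums(a2[, , k])
    if (any(cs <= 0)) stop("zero column norm in coefficient spectrum")
    vals[, , k] <- sqrt(sweep(a2[, , k], 2L, cs, "/"))
  }
  new("ConnectivityTensor", values = vals, method = "gpdc",
      freqs = as.numeric(freqs), channelNames = channelNames(model))
}

#' Band-average a connectivity tensor into a feature vector
#'
#' Averages tensor values within each band and flattens to a vector of
#' length `n_bands x n_channels^2`.  Ordering: band slowest, then sink, then
#' source fastest; names are `band:source->sink`.  The (band, source, sink)
#' index map is attached as attribute `indexMap`.
#'
#' @param tensor a [ConnectivityTensor-class].
#' @param bands band table as from [standardBands()].
#' @return Named numeric feature vector with attribute `indexMap`.
#' @export
featurize <- function(tensor, bands = standardBands()) {
  stopifnot(is(tensor, "ConnectivityTensor"))
  f <- tensor@freqs
  nc <- nChannels(tensor)
  cn <- channelNames(tensor)
  nb <- nrow(bands)
  out <- numeric(0); map <- NULL
  for (b in seq_len(nb)) {
    inBand <- f >= bands$low[b] &
      (if (b == nb) f <= bands$high[b] else f < bands$high[b])
    if (!any(inBand))
      stop(sprintf("band %s outside the tensor frequency grid", bands$label[b]))
    avg <- apply(tensor@values[, , inBand, drop = FALSE], c(1, 2), mean)
    # entry [i, j] is flow j -> i; flatten sink-major, source fastest
    for (i in seq_len(nc)) {
      v <- avg[i, ]
      names(v) <- sprintf("%s:%s->%s", bands$label[b], cn, cn[i])
      out <- c(out, v)
      map <- rbind(map, data.frame(band = bands$label[b], source = cn,
                                   sink = cn[i], stringsAsFactors = FALSE))
    }
  }
  attr(out, "indexMap") <- map
  attr(out, "method") <- tensor@method
  out
}
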