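test_that("amplitude normalization is the per-channel affine map to [0, 1]", {
  sig <- EEGSignal(cbind(c(2, 4, 6), c(0, 0.5, 1)), 250, c("a", "b"))
  out <- normalizeAmplitude(sig)
  expect_equal(signalData(out)[, "a"], c(0, 0.5, 1))
  expect_equal(signalData(out)[, "b"], c(0, 0.5, 1))   # already [0,1]: unchanged
  expect_true(out@isNormalized)
  # idempotence
  expect_equal(signalData(normalizeAmplitude(out)), signalData(out))
  # exact range on random data
  rnd <- whiteSignal(500, 2, seed = 1)
  z <- signalData(normalizeAmplitude(rnd))
  expect_equal(unname(apply(z, 2, min)), c(0, 0))
  expect_equal(unname(apply(z, 2, max)), c(1, 1))
})

test_that("a constant channel is rejected by name", {
  sig <- EEGSignal(cbind(rnorm(100), rep(2, 100)), 250, c("ok", "flat"))
  expect_error(normalizeAmplitude(sig), "flat")
})

test_that("connectivity is invariant to amplitude normalization", {
  set.seed(2)
  x <- matrix(rnorm(4000 * 3), ncol = 3) %*%
    matrix(c(1, .4, 0, 0, 1, .3, 0, 0, 1), 3, 3)
  sig <- EEGSignal(x, 250)
  p1 <- psiRaw(sig, band = c(8, 12))
  p2 <- psiRaw(normalizeAmplitude(sig), band = c(8, 12))
  expect_lt(max(abs(p1@psi - p2@psi)), 1e-8)
})

test_that("band-pass keeps pass-band tones and kills stop-band tones", {
  amp <- function(s) diff(range(signalData(s)[500:2000, 1])) / 2
  tone10 <- toneSignal(10)
  expect_equal(amp(bandpass(tone10)), 1, tolerance = 0.05)
  tone1 <- toneSignal(1)
  # attenuation measured via FFT amplitude ratio at the tone bin
  fftAmp <- function(s, f) {
    z <- Mod(fft(signalData(s)[, 1]))
    z[round(f * nSamples(s) / samplingRate(s)) + 1]
  }
  atten <- 20 * log10(fftAmp(bandpass(tone1), 1) / fftAmp(tone1, 1))
  expect_lt(atten, -30)
  expect_error(bandpass(toneSignal(10), low = 4, high = 200), "invalid band")
})

test_that("band-passed white noise concentrates its power in 4-32 Hz", {
  wn <- whiteSignal(12800, 1, seed = 3)
  filt <- bandpass(wn)
  S <- welchCPSD(filt, 256)
  psd <- Re(S@values[1, 1, ])
  inBand <- S@freqs >= 4 & S@freqs <= 32
  expect_lt(sum(psd[!inBand]) / sum(psd), 0.05)
})

test_that("the filter bank emits the seven 4 Hz bands in order", {
  sig <- toneSignal(10, n = 2500)
  fb <- filterBank(sig)
  expect_length(fb, 7L)
  expect_identical(names(fb),
                   c("[4-8]", "[8-12]", "[12-16]", "[16-20]",
                     "[20-24]", "[24-28]", "[28-32]"))
  pw <- vapply(fb, function(s) mean(signalData(s)^2), numeric(1))
  expect_identical(names(which.max(pw)), "[8-12]")
  expect_true(all(pw[-2] < 0.1 * pw[2]))
  zero <- EEGSignal(matrix(0, 600, 2), 250)
  fz <- filterBank(zero)
  expect_true(all(vapply(fz, function(s) max(abs(signalData(s))), numeric(1)) == 0))
})

test_that("filter-bank branches are near-orthogonal on white noise", {
  # branches share one source, so raw coherence is ill-defined where power
  # vanishes; orthogonality is assessed as normalized cross-branch power
  wn <- whiteSignal(12800, 1, seed = 4)
  fb <- filterBank(wn)
  pair <- EEGSignal(cbind(signalData(fb[["[4-8]"]]), signalData(fb[["[12-16]"]])),
                    250, c("b1", "b3"))
  S <- welchCPSD(pair, 256)
  overlap <- sum(Mod(S@values[1, 2, ])) /
    sqrt(sum(Re(S@values[1, 1, ])) * sum(Re(S@values[2, 2, ])))
  expect_lt(overlap, 0.05)
  # and each branch satisfies the band-pass stop-band contract
  for (b in c(1, 4, 7)) {
    Sb <- welchCPSD(fb[[b]], 256)
    psd <- Re(Sb@values[1, 1, ])
    lim <- attr(fb[[b]], "band")
    stopBand <- Sb@freqs < lim[1] / 2 | Sb@freqs > 1.5 * lim[2]
    expect_lt(sum(psd[stopBand]) / sum(psd), 0.01)
  }
})

test_that("window extraction follows the 0-based half-open convention", {
  sig <- whiteSignal(1000, 2, seed = 5)
  whole <- extractWindow(sig, 0, 1000)
  expect_equal(signalData(whole), signalData(sig))
  w <- extractWindow(sig, 500, 400)
  expect_equal(signalData(w), signalData(sig)[501:900, ])
  expect_error(extractWindow(sig, 999, 2), "out of range")
  # the standard analysis window covers 2.048 s starting at t = 2 s
  big <- whiteSignal(1500, 1, seed = 6)
  w2 <- extractWindow(big)   # defaults: start 500, length 512
  expect_equal(attr(w2, "windowStart") / samplingRate(big), 2)
  expect_equal(nSamples(w2) / samplingRate(big), 2.048)
})

test_that("normalization commutes with windowing up to a final renormalization", {
  sig <- whiteSignal(800, 2, seed = 7)
  a <- normalizeAmplitude(extractWindow(sig, 100, 400))
  b <- normalizeAmplitude(extractWindow(normalizeAmplitude(sig), 100, 400))
  expect_equal(signalData(a), signalData(b), tolerance = 1e-12)
})
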