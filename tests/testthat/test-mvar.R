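test_that("Yule-Walker recovers the generating coefficients", {
  gen <- MVARModel(list(matrix(c(0.4, 0.3, 0, 0.5), 2, 2),
                        matrix(c(-0.2, 0.1, 0, -0.15), 2, 2)))
  sig <- simulateMVAR(gen, 10000, seed = 1)
  fit <- fitMVAR(sig, 2)
  expect_lt(max(abs(fit@A[[1]] - gen@A[[1]])), 0.05)
  expect_lt(max(abs(fit@A[[2]] - gen@A[[2]])), 0.05)
  expect_equal(fit@noiseCov, diag(2), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("independent white noise fits to null coefficients", {
  sig <- whiteSignal(8000, 2, seed = 2)
  fit <- fitMVAR(sig, 2)
  for (r in 1:2)
    expect_lt(max(abs(fit@A[[r]][1, 2]), abs(fit@A[[r]][2, 1])), 3 / sqrt(8000))
})

test_that("over-specified orders put near-zero mass on extra lags", {
  gen <- unidirSpec(gain = 0.4, lag = 2)
  sig <- simulateMVAR(gen, 10000, seed = 3)
  fit <- fitMVAR(sig, 4)
  expect_lt(max(abs(fit@A[[3]])), 0.05)
  expect_lt(max(abs(fit@A[[4]])), 0.05)
})

test_that("degenerate fits are rejected", {
  x <- rnorm(500)
  dup <- EEGSignal(cbind(x, x), 250, c("a", "b"))
  expect_error(fitMVAR(dup, 2), "singular")
  expect_error(fitMVAR(whiteSignal(100, 2), 0), "order")
})

test_that("information-criterion order selection finds the generating order", {
  gen <- MVARModel(list(diag(0.4, 2), diag(-0.3, 2),
                        matrix(c(0.2, 0.25, 0.1, 0.15), 2, 2)))
  hits <- vapply(1:8, function(s) {
    sig <- simulateMVAR(gen, 4000, seed = 100 + s)
    as.integer(selectOrder(sig, maxOrder = 6))
  }, integer(1))
  expect_gte(mean(hits == 3L), 0.9)
  # white noise: low order dominates
  low <- vapply(1:8, function(s)
    as.integer(selectOrder(whiteSignal(2000, 2, seed = 200 + s), maxOrder = 5)),
    integer(1))
  expect_gte(mean(low == 1L), 0.6)
  expect_equal(selectOrder(whiteSignal(1000, 2, seed = 9), maxOrder = 1), 1L,
               ignore_attr = TRUE)
})

test_that("the transfer function inverts the coefficient spectrum", {
  # null model: identity at every frequency
  null <- MVARModel(list(matrix(0, 2, 2)))
  H <- transferFunction(null, freqs = c(5, 10, 20))
  for (k in 1:3) expect_equal(H[, , k], diag(2) + 0i)
  # scalar AR(1): |H|^2 = 1 / |1 - a e^{-i theta}|^2, maximal at f = 0
  ar1 <- MVARModel(list(matrix(0.5, 1, 1)))
  freqs <- c(0, 5, 10, 40)
  H1 <- transferFunction(ar1, freqs)
  theta <- 2 * pi * freqs / 250
  expect_equal(as.vector(Mod(H1[1, 1, ])^2),
               1 / Mod(1 - 0.5 * exp(-1i * theta))^2, tolerance = 1e-12)
  expect_equal(which.max(Mod(H1[1, 1, ])), 1L)
  # inverse contract on a random stable model
  gen <- MVARModel(list(matrix(c(0.4, 0.2, -0.1, 0.3), 2, 2)))
  H2 <- transferFunction(gen, 4:32)
  ab <- attr(H2, "Abar")
  for (k in seq_len(dim(H2)[3]))
    expect_lt(max(Mod(H2[, , k] %*% ab[, , k] - diag(2))), 1e-10)
})

test_that("DTF obeys its sink normalization and direction contract", {
  null <- MVARModel(list(diag(0.5, 3)))
  d0 <- dtf(null)
  for (i in 1:3) expect_equal(d0@values[i, i, ], rep(1, 29))
  expect_lt(max(d0@values[1, 2, ], d0@values[2, 1, ]), 1e-12)
  gen <- unidirSpec(gain = 0.5, lag = 1)
  fit <- fitMVAR(simulateMVAR(gen, 8000, seed = 4), 2)
  d <- dtf(fit)
  expect_true(all(d@values >= 0 & d@values <= 1))
  expect_gt(mean(d@values[2, 1, ]), mean(d@values[1, 2, ]))
  expect_lt(mean(d@values[1, 2, ]), 0.05)
  sums <- apply(d@values, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("PDC obeys its source normalization and direction contract", {
  null <- MVARModel(list(diag(0.5, 3)))
  g0 <- gpdc(null)
  for (j in 1:3) expect_equal(g0@values[j, j, ], rep(1, 29))
  gen <- unidirSpec(gain = 0.5, lag = 1)
  fit <- fitMVAR(simulateMVAR(gen, 8000, seed = 5), 2)
  g <- gpdc(fit)
  expect_true(all(g@values >= 0 & g@values <= 1))
  expect_gt(mean(g@values[2, 1, ]), mean(g@values[1, 2, ]))
  expect_lt(mean(g@values[1, 2, ]), 0.1)
  sums <- apply(g@values^2, c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("variance-weighted PDC is invariant to per-channel rescaling, DTF to common rescaling", {
  gen <- MVARModel(list(matrix(c(0.5, 0.3, 0, 0.4), 2, 2)))
  sig <- simulateMVAR(gen, 8000, seed = 6)
  scaled <- EEGSignal(sweep(signalData(sig), 2, c(1, 7), "*"), 250)
  common <- EEGSignal(signalData(sig) * 3.7, 250)
  g1 <- gpdc(fitMVAR(sig, 2), generalized = TRUE)
  g2 <- gpdc(fitMVAR(scaled, 2), generalized = TRUE)
  expect_lt(max(abs(g1@values - g2@values)), 1e-10)
  d1 <- dtf(fitMVAR(sig, 2))
  d2 <- dtf(fitMVAR(common, 2))
  expect_lt(max(abs(d1@values - d2@values)), 1e-10)
})

test_that("direction recovery is reliable across simulated unidirectional couplings", {
  set.seed(7)
  hits <- replicate(20, {
    gain <- runif(1, 0.3, 0.5)
    gen <- unidirSpec(gain = gain, lag = sample(1:3, 1))
    fit <- fitMVAR(simulateMVAR(gen, 5000), 4)
    d <- dtf(fit); g <- gpdc(fit)
    c(mean(d@values[2, 1, ]) > mean(d@values[1, 2, ]),
      mean(g@values[2, 1, ]) > mean(g@values[1, 2, ]))
  })
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})

test_that("band-averaged features have the documented size and ordering", {
  gen <- conditionSpecFixture()
  fit <- fitMVAR(simulateMVAR(gen, 4000, seed = 8), 4)
  v <- featurize(dtf(fit))
  expect_length(v, 7 * 8^2)
  map <- attr(v, "indexMap")
  expect_equal(nrow(map), 448L)
  expect_identical(names(v)[1], "[4-8]:F3->F3")
  # 2 channels, 1 band
  small <- dtf(fitMVAR(whiteSignal(2000, 2, seed = 9), 2))
  v2 <- featurize(small, bands = data.frame(low = 8, high = 12, label = "[8-12]"))
  expect_length(v2, 4L)
  # constant tensor averages to the constant
  const <- new("ConnectivityTensor",
               values = array(0.25, c(2, 2, 29)), method = "dtf",
               freqs = as.numeric(4:32), channelNames = c("a", "b"))
  expect_true(all(featurize(const) == 0.25))
})
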