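makeClouds <- function(n = 60, d = 24, delta = 5, seed = 1) {
  set.seed(seed)
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * d), n) + outer(as.numeric(labels == "b") * delta,
                                       rep(1 / sqrt(d), d))
  list(X = X, y = labels)
}

test_that("a duplicated training point is its own nearest neighbour", {
  cl <- makeClouds(seed = 2)
  pred <- trainPredict(cl$X, cl$y, cl$X[c(3, 40), , drop = FALSE],
                       classifierConfig("knn", k = 1))
  expect_identical(as.character(pred), cl$y[c(3, 40)])
})

test_that("both back-ends separate well-separated Gaussian clouds", {
  tr <- makeClouds(seed = 3); te <- makeClouds(seed = 4)
  for (cfg in list(classifierConfig("knn"), classifierConfig("svm", sigma = 6))) {
    pred <- trainPredict(tr$X, tr$y, te$X, cfg)
    expect_gte(mean(as.character(pred) == te$y), 0.95)
  }
})

test_that("permuted labels bring accuracy back to chance", {
  tr <- makeClouds(n = 80, seed = 5)
  set.seed(6)
  acc <- vapply(1:10, function(i) {
    yp <- sample(tr$y)
    ev <- looEvaluate(tr$X, yp, classifierConfig("knn"), nOut = 24)
    ev$accuracy
  }, numeric(1))
  expect_gte(mean(acc), 35)
  expect_lte(mean(acc), 65)
})

test_that("single-class training is rejected", {
  cl <- makeClouds(seed = 7)
  expect_error(trainPredict(cl$X, rep("a", nrow(cl$X)), cl$X[1, , drop = FALSE]),
               "single class")
})

test_that("leave-one-out is perfect on a separable table and warns on twins", {
  cl <- makeClouds(n = 30, delta = 8, seed = 8)
  ev <- looEvaluate(cl$X, cl$y, classifierConfig("knn", k = 1), nOut = 10)
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$nRecords, 30L)
  # duplicated records leak through k = 1 neighbours: flagged, still 100%
  X2 <- rbind(cl$X, cl$X); y2 <- c(cl$y, cl$y)
  expect_warning(ev2 <- looEvaluate(X2, y2, classifierConfig("knn", k = 1),
                                    nOut = 10), "twin leakage")
  expect_equal(ev2$accuracy, 100)
})

test_that("leave-one-out accuracy is invariant to record order and affine feature maps", {
  cl <- makeClouds(n = 40, delta = 3, seed = 9)
  base <- looEvaluate(cl$X, cl$y, classifierConfig("knn"), nOut = 12)
  perm <- sample(40)
  shuffled <- looEvaluate(cl$X[perm, ], cl$y[perm], classifierConfig("knn"),
                          nOut = 12)
  expect_equal(shuffled$accuracy, base$accuracy)
  rescaled <- looEvaluate(sweep(cl$X, 2, seq_len(24), "*") + 3, cl$y,
                          classifierConfig("knn"), nOut = 12)
  expect_equal(rescaled$accuracy, base$accuracy)
})

test_that("SVM width controls smoothness down to near-constant prediction", {
  cl <- makeClouds(n = 60, delta = 4, seed = 10)
  te <- makeClouds(n = 60, delta = 4, seed = 11)
  accAt <- function(sigma) {
    pred <- trainPredict(cl$X, cl$y, te$X, classifierConfig("svm", sigma = sigma))
    mean(as.character(pred) == te$y)
  }
  expect_gte(accAt(6), 0.9)
  # extreme width degrades towards a near-constant vote
  predWide <- trainPredict(cl$X, cl$y, te$X,
                           classifierConfig("svm", sigma = 1e6))
  expect_lte(length(unique(as.character(predWide))), 2L)
})

test_that("nested fusion follows the quadrant product rule and its bookkeeping", {
  expect_identical(as.character(nestedFuse("positive", "excited")),
                   "positive-excited")
  fused <- nestedFuse(c("positive", NA, "negative"),
                      c("calm", "excited", NA))
  expect_identical(as.character(fused), c("positive-calm", NA, NA))
  expect_equal(sum(!is.na(fused)), 1L)
  expect_error(nestedFuse("positive", c("calm", "excited")), "equal length")
})

test_that("composite accuracy is the product of independent stream accuracies", {
  set.seed(12)
  n <- 4000
  truthV <- sample(c("negative", "positive"), n, TRUE)
  truthA <- sample(c("calm", "excited"), n, TRUE)
  pv <- 0.9; pa <- 0.8
  flip <- function(x, p, lv) ifelse(runif(n) < p, x, setdiff(lv, x)[1])
  predV <- vapply(truthV, function(x)
    if (runif(1) < pv) x else setdiff(c("negative", "positive"), x), "")
  predA <- vapply(truthA, function(x)
    if (runif(1) < pa) x else setdiff(c("calm", "excited"), x), "")
  fused <- nestedFuse(predV, predA)
  truth <- nestedFuse(truthV, truthA)
  expect_equal(mean(fused == truth), pv * pa, tolerance = 0.05)
})

test_that("configuration validation rejects bad settings", {
  expect_error(classifierConfig("knn", k = 2), "odd")
  expect_error(classifierConfig("svm", sigma = 0), "sigma")
})
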