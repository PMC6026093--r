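test_that("the SAM threshold rule matches a hand-computed enumeration of all 81 pairs", {
  grid <- expand.grid(v = 1:9, a = 1:9)
  out <- labelValenceArousal(grid$v, grid$a)
  # independent restatement of the rule
  expectedV <- ifelse(grid$v <= 3, "negative", ifelse(grid$v >= 7, "positive", NA))
  expectedA <- ifelse(grid$a <= 3, "calm", ifelse(grid$a >= 7, "excited", NA))
  expect_identical(as.character(out$valenceClass), expectedV)
  expect_identical(as.character(out$arousalClass), expectedA)
  # boundary behaviour
  b <- labelValenceArousal(c(2, 5, 7), c(8, 5, 3))
  expect_identical(as.character(b$valenceClass), c("negative", NA, "positive"))
  expect_identical(as.character(b$arousalClass), c("excited", NA, "calm"))
  expect_identical(b$excludedReason[2], "neutral valence and arousal")
  expect_error(labelValenceArousal(0, 5), "\\[1, 9\\]")
})

test_that("labelling is permutation-equivariant", {
  set.seed(1)
  v <- sample(1:9, 30, TRUE); a <- sample(1:9, 30, TRUE)
  perm <- sample(30)
  direct <- labelValenceArousal(v[perm], a[perm])
  indirect <- labelValenceArousal(v, a)[perm, ]
  rownames(indirect) <- NULL
  expect_identical(direct, indirect)
})

test_that("PSS grouping uses exact mu +/- sigma/2 cuts", {
  g <- stressGroup(c(10, 24, 40))
  expect_identical(g$group, c("stress_free", "middle", "stressed"))
  scores <- c(15, 18, 21, 22, 24, 25, 27, 29, 31, 35)
  g2 <- stressGroup(scores)
  expect_equal(g2$lowCut, mean(scores) - sd(scores) / 2)
  expect_equal(g2$highCut, mean(scores) + sd(scores) / 2)
  expect_identical(g2$group,
                   ifelse(scores < g2$lowCut, "stress_free",
                          ifelse(scores > g2$highCut, "stressed", "middle")))
  expect_error(stressGroup(rep(24, 5)), "zero variance")
  expect_error(stressGroup(24), "at least 2")
})

test_that("PSS grouping is invariant under adding a constant to every score", {
  set.seed(2)
  scores <- sample(10:40, 12)
  expect_identical(stressGroup(scores)$group, stressGroup(scores + 7)$group)
})

test_that("Fisher ranking orders features by class separability", {
  set.seed(3)
  n <- 40
  labels <- rep(c("a", "b"), each = n / 2)
  sep <- ifelse(labels == "a", 0, 10) + rnorm(n, sd = 0.1)  # disjoint supports
  weak <- ifelse(labels == "a", 0, 1) + rnorm(n)
  same <- rnorm(n)
  const <- rep(5, n)
  X <- cbind(weak = weak, same = same, sep = sep, const = const)
  r <- rankFeatures(X, labels)
  expect_identical(colnames(X)[r$index[1]], "sep")
  expect_identical(colnames(X)[r$index[4]], "const")
  expect_identical(r$score[4], 0)
  # brute-force recomputation of every score
  brute <- apply(X, 2, function(f) {
    m <- tapply(f, labels, mean); v <- tapply(f, labels, var)
    num <- (m[1] - m[2])^2
    if (num == 0 && v[1] + v[2] == 0) 0 else num / (v[1] + v[2])
  })
  expect_equal(r$score, unname(sort(brute, decreasing = TRUE)))
  expect_error(rankFeatures(X, rep("a", n)), "2 classes")
})

test_that("permuted labels wipe out the separability signal", {
  set.seed(4)
  n <- 60
  labels <- rep(c("a", "b"), each = n / 2)
  X <- cbind(matrix(rnorm(n * 20), n),
             strong = ifelse(labels == "a", 0, 3) + rnorm(n, sd = .5))
  top <- rankFeatures(X, labels)$score[1]
  permTop <- vapply(1:20, function(i)
    rankFeatures(X, sample(labels))$score[1], numeric(1))
  expect_gt(top, max(permTop))
})

test_that("top-set selection keeps rank order and traceability", {
  set.seed(5)
  X <- matrix(rnorm(30 * 50), 30)
  colnames(X) <- paste0("f", 1:50)
  labels <- rep(c("a", "b"), 15)
  r <- rankFeatures(X, labels)
  sel <- selectTop(X, r, 24)
  expect_equal(ncol(sel), 24L)
  expect_identical(colnames(sel), paste0("f", r$index[1:24]))
  expect_identical(attr(sel, "selected"), r$index[1:24])
  all50 <- selectTop(X, r, 50)
  expect_setequal(colnames(all50), colnames(X))
  expect_error(selectTop(X, r, 0), "nOut")
  expect_error(selectTop(X, r, 51), "exceeds")
})

test_that("top-set selection is stable across subsamples of a separable table", {
  set.seed(6)
  n <- 80
  labels <- rep(c("a", "b"), each = n / 2)
  signal <- outer(ifelse(labels == "a", 0, 1), c(rep(3, 12), rep(0, 38)))
  X <- signal + matrix(rnorm(n * 50), n)
  odd <- seq(1, n, 2); even <- seq(2, n, 2)
  topA <- rankFeatures(X[odd, ], labels[odd])$index[1:12]
  topB <- rankFeatures(X[even, ], labels[even])$index[1:12]
  expect_gte(length(intersect(topA, topB)) / 12, 0.5)
})
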