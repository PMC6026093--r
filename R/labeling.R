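#' Binary valence/arousal labels from SAM responses
#'
#' Applies the threshold rule: valence <= 3 -> `"negative"` (class 1),
#' valence >= 7 -> `"positive"` (class 2), intermediate values are neutral
#' and excluded; arousal <= 3 -> `"calm"`, arousal >= 7 -> `"excited"`,
#' otherwise excluded.  Vectorized and total on valid inputs.
#'
#' @param valence,arousal integer vectors in [1, 9] (recycled to common
#'   length).
#' @return data.frame with columns `valence`, `arousal`, `valenceClass`,
#'   `arousalClass` (factors, `NA` = excluded) and `excludedReason`.
#' @examples
#' labelValenceArousal(c(2, 5, 7), c(8, 5, 3))
#' @export
labelValenceArousal <- function(valence, arousal) {
  n <- max(length(valence), length(arousal))
  valence <- rep_len(valence, n); arousal <- rep_len(arousal, n)
  if (any(valence < 1 | valence > 9 | arousal < 1 | arousal > 9))
    stop("SAM responses must lie in [1, 9]")
  vc <- ifelse(valence <= 3, "negative", ifelse(valence >= 7, "positive", NA))
  ac <- ifelse(arousal <= 3, "calm", ifelse(arousal >= 7, "excited", NA))
  reason <- ifelse(is.na(vc) & is.na(ac), "neutral valence and arousal",
            ifelse(is.na(vc), "neutral valence",
            ifelse(is.na(ac), "neutral arousal", "")))
  data.frame(valence = valence, arousal = arousal,
             valenceClass = factor(vc, levels = c("negative", "positive")),
             arousalClass = factor(ac, levels = c("calm", "excited")),
             excludedReason = reason, stringsAsFactors = FALSE)
}

#' Stress grouping from PSS-14 totals
#'
#' Computes the sample mean and SD of the scores and assigns each subject to
#' `stress_free` (score < mu - sigma/2), `stressed` (score > mu + sigma/2)
#' or `middle`.  Cut points are kept exact (unrounded) by default.
#'
#' @param pssScores integer vector of PSS-14 totals in [0, 56], length >= 2.
#' @param roundCuts round the cut points to integers before grouping
#'   (default `FALSE`).
#' @return A list with `mean`, `sd`, `lowCut`, `highCut` and the per-subject
#'   `group` character vector.
#' @examples
#' stressGroup(c(10, 24, 40))$group
#' @export
stressGroup <- function(pssScores, roundCuts = FALSE) {
  if (length(pssScores) < 2L) stop("need at least 2 scores")
  if (any(pssScores < 0 | pssScores > 56)) stop("PSS totals must lie in [0, 56]")
  mu <- mean(pssScores); sigma <- stats::sd(pssScores)
  if (sigma == 0) stop("zero variance in PSS scores: no grouping possible")
  lowCut <- mu - sigma / 2; highCut <- mu + sigma / 2
  if (roundCuts) { lowCut <- round(lowCut); highCut <- round(highCut) }
  group <- ifelse(pssScores < lowCut, "stress_free",
           ifelse(pssScores > highCut, "stressed", "middle"))
  list(mean = mu, sd = sigma, lowCut = lowCut, highCut = highCut, group = group)
}

#' Rank features by Fisher class-separability score
#'
#' Per-feature score `(mu1 - mu2)^2 / (s1^2 + s2^2)` between the two label
#' classes, ranked descending with deterministic tie-break by feature index.
#' A feature identical in both classes scores 0; a feature with zero pooled
#' variance but distinct class means scores `Inf` (perfectly separating).
#'
#' @param features numeric matrix, records x features.
#' @param labels binary factor/vector, one label per record.
#' @return data.frame with columns `index`, `score`, ordered by decreasing
#'   score.
#' @export
rankFeatures <- function(features, labels) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must contain exactly 2 classes (got ", nlevels(labels), ")")
  if (min(table(labels)) < 2L) stop("need >= 2 records per class")
  g1 <- features[labels == levels(labels)[1], , drop = FALSE]
  g2 <- features[labels == levels(labels)[2], , drop = FALSE]
  num <- (colMeans(g1) - colMeans(g2))^2
  den <- apply(g1, 2L, stats::var) + apply(g2, 2L, stats::var)
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  ord <- order(score, seq_along(score), decreasing = c(TRUE, FALSE), method = "radix")
  data.frame(index = ord, score = score[ord])
}

#' Keep the top-ranked feature columns
#'
#' @param features numeric matrix, records x features.
#' @param ranking output of [rankFeatures()].
#' @param nOut number of columns to retain (default 24).
#' @return The reduced matrix (columns in rank order); selected indices in
#'   attribute `selected`.
#' @export
selectTop <- function(features, ranking, nOut = 24L) {
  features <- as.matrix(features)
  nOut <- as.integer(nOut)
  if (nOut < 1L) stop("nOut must be >= 1")
  if (nOut > ncol(features))
    stop(sprintf("nOut = %d exceeds available features (%d)", nOut, ncol(features)))
  idx <- ranking$index[seq_len(nOut)]
  out <- features[, idx, drop = FALSE]
  attr(out, "selected") <- idx
  out
}
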