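#' Classifier configuration
#'
#' @param kind `"knn"` or `"svm"`.
#' @param k neighbour count for KNN (odd, default 3).
#' @param sigma RBF kernel width for the SVM under
#'   `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`; the study defaults are 6
#'   for valence and 3.5 for arousal detection.
#' @param cost SVM soft-margin constant (default 1).
#' @return A list with class `ClassifierConfig`.
#' @export
classifierConfig <- function(kind = c("knn", "svm"), k = 3L, sigma = 6,
                             cost = 1) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (kind == "knn" && (k < 1L || k %% 2L == 0L))
    stop("knn k must be odd and >= 1")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(kind = kind, k = k, sigma = sigma, cost = cost),
            class = "ClassifierConfig")
}

# z-score columns by training statistics; zero-variance columns pass through.
standardizeBy <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sdv, "/"))
}

#' Train on one set, predict another
#'
#' Features are standardized on the training statistics only, then either a
#' majority-vote KNN (Euclidean metric) or a soft-margin SVM with Gaussian
#' RBF kernel `exp(-||x-y||^2 / (2 sigma^2))` is applied.  Deterministic
#' given data and configuration.
#'
#' @param train numeric matrix of training records x features.
#' @param labels training labels (binary factor/vector).
#' @param test numeric matrix of records to predict.
#' @param config a [classifierConfig()].
#' @return Factor of predicted labels, one per test record.
#' @export
trainPredict <- function(train, labels, test, config = classifierConfig()) {
  train <- as.matrix(train); test <- as.matrix(test)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("training set contains a single class")
  z <- standardizeBy(train, test)
  if (config$kind == "knn") {
    class::knn(z$train, z$test, labels, k = config$k)
  } else {
    fit <- e1071::svm(z$train, labels, kernel = "radial",
                      gamma = 1 / (2 * config$sigma^2), cost = config$cost,
                      scale = FALSE)
    stats::predict(fit, z$test)
  }
}

#' Leave-one-out evaluation with in-fold feature selection
#'
#' For each record: rank features on the remaining records (Fisher score),
#' keep the top `nOut`, standardize on the training fold, train, and predict
#' the held-out record.  Feature selection inside the fold avoids selection
#' leakage; `leaky = TRUE` reproduces the optimistic variant that selects
#' once on all records.
#'
#' @param features numeric matrix, records x features.
#' @param labels binary labels, one per record (`NA` records are dropped).
#' @param config a [classifierConfig()].
#' @param nOut number of features kept per fold (default 24; capped at the
#'   number available).
#' @param leaky select features once on the full data set (default `FALSE`).
#' @return List: `accuracy` (percent correct), `predictions`, `truth`,
#'   `confusion`, `nRecords`, `skippedFolds`.
#' @export
looEvaluate <- function(features, labels, config = classifierConfig(),
                        nOut = 24L, leaky = FALSE) {
  features <- as.matrix(features)
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- factor(labels[keep])
  labels <- droplevels(labels)
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 labelled records for leave-one-out")
  if (anyDuplicated(features))
    warning("duplicate feature records present: leave-one-out accuracy may be optimistic (twin leakage)")
  nOut <- min(as.integer(nOut), ncol(features))
  globalSel <- if (leaky)
    rankFeatures(features, labels)$index[seq_len(nOut)] else NULL
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  skipped <- integer(0)
  for (i in seq_len(n)) {
    trLab <- labels[-i]
    if (nlevels(droplevels(trLab)) < 2L) { skipped <- c(skipped, i); next }
    sel <- if (leaky) globalSel else
      rankFeatures(features[-i, , drop = FALSE], trLab)$index[seq_len(nOut)]
    pred[i] <- trainPredict(features[-i, sel, drop = FALSE], trLab,
                            features[i, sel, drop = FALSE], config)
  }
  done <- setdiff(seq_len(n), skipped)
  acc <- 100 * mean(pred[done] == labels[done])
  list(accuracy = acc,
       predictions = pred, truth = labels,
       confusion = table(truth = labels[done], predicted = pred[done]),
       nRecords = length(done), skippedFolds = skipped)
}

#' Fuse binary valence and arousal streams into a 4-class emotion label
#'
#' The nested two-binary-classifier scheme: a record's quadrant label is the
#' combination of its valence (`negative`/`positive`) and arousal
#' (`calm`/`excited`) predictions; records excluded (NA) in either stream
#' are excluded from the composite.
#'
#' @param valence factor/character of valence predictions.
#' @param arousal factor/character of arousal predictions.
#' @return Factor of quadrant labels `valence-arousal` with `NA` where
#'   either stream is missing.
#' @examples
#' nestedFuse(c("positive", NA), c("excited", "calm"))
#' @export
nestedFuse <- function(valence, arousal) {
  valence <- as.character(valence); arousal <- as.character(arousal)
  if (length(valence) != length(arousal))
    stop("valence and arousal predictions must have equal length")
  out <- ifelse(is.na(valence) | is.na(arousal), NA_character_,
                paste(valence, arousal, sep = "-"))
  lv <- c("negative-calm", "negative-excited", "positive-calm", "positive-excited")
  factor(out, levels = lv)
}
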