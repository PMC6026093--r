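#' Extract connectivity features for one recording
#'
#' Standard preprocessing (amplitude normalization to [0, 1], zero-phase
#' 4-32 Hz band-pass) followed by one of the three directed-connectivity
#' feature extractors on the 7-band grid:
#' \describe{
#'   \item{psi}{jackknife-normalized phase slope index per band
#'     ([psiFeaturize()]).}
#'   \item{dtf}{normalized DTF of a Yule-Walker MVAR fit, band-averaged
#'     ([dtf()], [featurize()]).}
#'   \item{gpdc}{partial directed coherence of the same fit
#'     ([gpdc()], [featurize()]).}
#' }
#' All three return `7 x n_channels^2` features.
#'
#' @param sig an [EEGSignal-class].
#' @param method `"psi"`, `"dtf"` or `"gpdc"`.
#' @param order MVAR order for dtf/gpdc (default 7).
#' @param segLength Welch segment length for psi (default 256).
#' @param preprocess apply normalization + band-pass first (default `TRUE`).
#' @return Named feature vector of length `7 * nChannels(sig)^2`.
#' @export
extractFeatures <- function(sig, method = c("psi", "dtf", "gpdc"),
                            order = 7L, segLength = 256L, preprocess = TRUE) {
  method <- match.arg(method)
  if (preprocess)
    sig <- bandpass(normalizeAmplitude(sig))
  if (method == "psi") {
    psiFeaturize(sig, segLength = segLength)
  } else {
    model <- fitMVAR(sig, order = order)
    tensor <- if (method == "dtf") dtf(model) else gpdc(model)
    featurize(tensor)
  }
}

#' Feature table for a whole cohort
#'
#' One row per subject x emotional condition: connectivity features plus the
#' SAM-derived binary labels, PSS total and stress group.
#'
#' @param cohort list of [SubjectRecord-class].
#' @param method feature extractor, see [extractFeatures()].
#' @param ... passed to [extractFeatures()].
#' @return List with `features` (records x features matrix) and `meta`
#'   (data.frame: subject, condition, valence, arousal, valenceClass,
#'   arousalClass, pss, group).
#' @export
cohortFeatureTable <- function(cohort, method = c("psi", "dtf", "gpdc"), ...) {
  method <- match.arg(method)
  feats <- list(); meta <- list()
  for (rec in cohort) {
    for (cond in names(rec@signals)) {
      v <- extractFeatures(rec@signals[[cond]], method = method, ...)
      id <- paste(rec@subjectId, cond, sep = ".")
      feats[[id]] <- v
      sam <- rec@sam[[cond]]
      meta[[id]] <- data.frame(subject = rec@subjectId, condition = cond,
                               valence = sam[1], arousal = sam[2],
                               pss = rec@pssScore, group = rec@stressGroup,
                               stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  meta <- do.call(rbind, meta)
  lab <- labelValenceArousal(meta$valence, meta$arousal)
  meta$valenceClass <- lab$valenceClass
  meta$arousalClass <- lab$arousalClass
  list(features = features, meta = meta)
}
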