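#' Two-tailed Welch t-test
#'
#' Unpaired t-test assuming unequal variances:
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b numeric samples (each >= 2 values; positive variance in at
#'   least one).
#' @return List with `t`, `df`, `p`, `meanA`, `meanB`, `nA`, `nB`.
#' @export
welchTtest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both samples degenerate (zero variance)")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanA = mean(a), meanB = mean(b),
       nA = length(a), nB = length(b))
}

#' Per-subject PSI flux table for a cohort
#'
#' Computes the averaged-PSI channel flux ([fluxMap()]) per subject, either
#' on the resting-state recording or on the emotional-condition recordings
#' whose SAM valence passes the filter (`"positive"`: valence >= 7,
#' `"negative"`: valence <= 3; several qualifying conditions are averaged).
#' Subjects with no qualifying recording are dropped.
#'
#' @param cohort list of [SubjectRecord-class] (as from [generateCohort()]).
#' @param condition `"resting"`, `"positive"` or `"negative"`.
#' @param window,duration,band passed to [fluxMap()].  `duration` defaults
#'   to 50 s, capped at the shortest qualifying recording.
#' @return data.frame: subject, group, pss, one column per channel.
#' @export
cohortFluxTable <- function(cohort, condition = c("resting", "positive", "negative"),
                            window = 2, duration = 50, band = c(4, 32)) {
  condition <- match.arg(condition)
  rows <- list()
  for (rec in cohort) {
    sigs <- if (condition == "resting") list(rec@restingSignal)
    else {
      q <- vapply(rec@sam, function(v)
        if (condition == "positive") v[1] >= 7 else v[1] <= 3, logical(1))
      rec@signals[q]
    }
    if (!length(sigs)) next
    fl <- rowMeans(vapply(sigs, function(s) {
      d <- min(duration, floor(nSamples(s) / samplingRate(s) / window) * window)
      fluxMap(s, window = window, duration = d, band = band)
    }, numeric(nChannels(rec@restingSignal))))
    rows[[rec@subjectId]] <- data.frame(subject = rec@subjectId,
                                        group = rec@stressGroup,
                                        pss = rec@pssScore,
                                        t(fl), check.names = FALSE,
                                        stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no subject qualifies for condition filter ", condition)
  do.call(rbind, rows)
}

#' Compare stressed vs stress-free flux maps per channel
#'
#' Welch two-tailed unpaired t-test of the per-channel PSI flux between the
#' stressed and stress-free groups of a cohort.  No multiple-testing
#' correction is applied by default; `adjust` selects one.
#'
#' @param fluxTable output of [cohortFluxTable()].
#' @param adjust p-value adjustment method (`"none"`, `"bonferroni"`,
#'   `"BH"`, ... as in [stats::p.adjust()]).
#' @return data.frame per channel: t, df, p (optionally adjusted),
#'   group means and sizes; group sizes in attributes `nStressed`,
#'   `nStressFree`.
#' @export
compareGroups <- function(fluxTable, adjust = "none") {
  chans <- setdiff(colnames(fluxTable), c("subject", "group", "pss"))
  a <- fluxTable[fluxTable$group == "stressed", chans, drop = FALSE]
  b <- fluxTable[fluxTable$group == "stress_free", chans, drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop(sprintf("empty/degenerate group after filtering (stressed n=%d, stress-free n=%d)",
                 nrow(a), nrow(b)))
  res <- do.call(rbind, lapply(chans, function(ch) {
    ht <- welchTtest(a[[ch]], b[[ch]])
    data.frame(channel = ch, t = ht$t, df = ht$df, p = ht$p,
               meanStressed = ht$meanA, meanStressFree = ht$meanB,
               stringsAsFactors = FALSE)
  }))
  if (adjust != "none") res$pAdjusted <- stats::p.adjust(res$p, method = adjust)
  attr(res, "nStressed") <- nrow(a)
  attr(res, "nStressFree") <- nrow(b)
  res
}
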