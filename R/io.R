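#' Write / read a multichannel signal as wide CSV
#'
#' Wide CSV layout: first column `time` (seconds), one column per channel.
#' The sampling rate is inferred on read from the time column (median
#' spacing) unless given explicitly; channel matching against a requested
#' montage is case-insensitive.
#'
#' @param sig an [EEGSignal-class].
#' @param path file path.
#' @return `writeSignalCSV` returns `path` invisibly; `readSignalCSV`
#'   returns an [EEGSignal-class].
#' @export
writeSignalCSV <- function(sig, path) {
  stopifnot(is(sig, "EEGSignal"))
  df <- data.frame(time = (seq_len(nSamples(sig)) - 1L) / samplingRate(sig),
                   signalData(sig), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignalCSV
#' @param samplingRate sampling rate in Hz; inferred from the `time` column
#'   when `NULL`.
#' @param channels optional montage: required channel names
#'   (case-insensitive); columns are reordered to match and a missing
#'   channel is an error.
#' @export
readSignalCSV <- function(path, samplingRate = NULL, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- which(tolower(names(df)) == "time")
  if (length(tcol) != 1L) stop("wide CSV must have a single 'time' column")
  fs <- 1 / stats::median(diff(df[[tcol]]))
  if (!is.null(samplingRate)) {
    if (abs(fs - samplingRate) > 1e-6 * samplingRate)
      warning(sprintf("time column implies %.6g Hz, config says %g Hz", fs, samplingRate))
    fs <- samplingRate
  }
  x <- as.matrix(df[, -tcol, drop = FALSE])
  if (!is.null(channels)) {
    idx <- match(tolower(channels), tolower(colnames(x)))
    if (anyNA(idx))
      stop("channel(s) missing from file: ",
           paste(channels[is.na(idx)], collapse = ", "))
    x <- x[, idx, drop = FALSE]
    colnames(x) <- channels
  }
  EEGSignal(x, fs)
}

#' Write a synthetic cohort to disk
#'
#' One wide CSV per subject-condition (`<subject>_<condition>.csv`,
#' including `resting`) plus a tidy `metadata.csv` with columns subject_id,
#' condition, valence, arousal, pss, group.
#'
#' @param cohort list of [SubjectRecord-class].
#' @param dir output directory (created if needed).
#' @return The metadata data.frame, invisibly.
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (rec in cohort) {
    for (cond in names(rec@signals)) {
      writeSignalCSV(rec@signals[[cond]],
                     file.path(dir, sprintf("%s_%s.csv", rec@subjectId, cond)))
      sam <- rec@sam[[cond]]
      meta[[paste(rec@subjectId, cond)]] <-
        data.frame(subject_id = rec@subjectId, condition = cond,
                   valence = sam[1], arousal = sam[2],
                   pss = rec@pssScore, group = rec@stressGroup,
                   stringsAsFactors = FALSE)
    }
    writeSignalCSV(rec@restingSignal,
                   file.path(dir, sprintf("%s_resting.csv", rec@subjectId)))
    meta[[paste(rec@subjectId, "resting")]] <-
      data.frame(subject_id = rec@subjectId, condition = "resting",
                 valence = NA_integer_, arousal = NA_integer_,
                 pss = rec@pssScore, group = rec@stressGroup,
                 stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read a cohort written by [writeCohortCSV()]
#'
#' @param dir directory containing the per-recording CSVs and
#'   `metadata.csv`.
#' @param samplingRate expected sampling rate (checked against the files).
#' @return List of [SubjectRecord-class].
#' @export
readCohortCSV <- function(dir, samplingRate = NULL) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  cohort <- list()
  for (sid in unique(meta$subject_id)) {
    rows <- meta[meta$subject_id == sid, ]
    sigs <- list(); sam <- list(); rest <- NULL
    for (k in seq_len(nrow(rows))) {
      cond <- rows$condition[k]
      sig <- readSignalCSV(file.path(dir, sprintf("%s_%s.csv", sid, cond)),
                           samplingRate = samplingRate)
      if (cond == "resting") rest <- sig
      else {
        sigs[[cond]] <- sig
        sam[[cond]] <- c(rows$valence[k], rows$arousal[k])
      }
    }
    if (is.null(rest)) stop("subject ", sid, " has no resting recording")
    cohort[[sid]] <- new("SubjectRecord", subjectId = sid,
                         pssScore = as.integer(rows$pss[1]),
                         stressGroup = rows$group[1],
                         signals = sigs, sam = sam, restingSignal = rest)
  }
  cohort
}
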