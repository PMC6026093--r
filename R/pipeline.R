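#' Run the full analysis pipeline
#'
#' End-to-end: cohort (generated from `config` or read from `inputDir`) ->
#' preprocessing -> connectivity features per method -> SAM labelling ->
#' in-fold feature selection -> leave-one-out classification of valence and
#' arousal (KNN and RBF-SVM) with nested 4-class fusion -> Welch t-tests of
#' averaged-PSI flux between stress groups.  All artifacts (feature tables,
#' evaluation reports, group statistics, manifest) are written under
#' `outDir`.
#'
#' @param config a [cohortConfig()]; ignored when `inputDir` is given.
#' @param inputDir optional directory with a cohort written by
#'   [writeCohortCSV()].
#' @param outDir output directory.
#' @param methods connectivity methods to run (subset of psi/dtf/gpdc).
#' @param classifiers classifier kinds to run (subset of knn/svm).
#' @param nOut features kept per fold (default 24).
#' @param sigmaValence,sigmaArousal RBF widths for the two SVM streams
#'   (defaults 6 and 3.5).
#' @param fluxConditions flux-map group comparisons to run.
#' @return Invisible list with `features`, `evaluation`, `groupStats` and
#'   the artifact directory.
#' @export
runPipeline <- function(config = cohortConfig(), inputDir = NULL,
                        outDir = tempfile("eegconn_run_"),
                        methods = c("psi", "dtf", "gpdc"),
                        classifiers = c("knn", "svm"),
                        nOut = 24L, sigmaValence = 6, sigmaArousal = 3.5,
                        fluxConditions = c("resting", "positive", "negative")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is.null(inputDir)) generateCohort(config)
            else readCohortCSV(inputDir)
  evaluation <- list(); featureTables <- list()
  for (method in methods) {
    tab <- cohortFeatureTable(cohort, method = method)
    featureTables[[method]] <- tab
    utils::write.csv(
      data.frame(tab$meta, tab$features, check.names = FALSE),
      file.path(outDir, sprintf("features_%s.csv", method)), row.names = FALSE)
    for (clf in classifiers) {
      cfgV <- if (clf == "svm") classifierConfig("svm", sigma = sigmaValence)
              else classifierConfig("knn")
      cfgA <- if (clf == "svm") classifierConfig("svm", sigma = sigmaArousal)
              else classifierConfig("knn")
      evV <- looEvaluate(tab$features, tab$meta$valenceClass, cfgV, nOut = nOut)
      evA <- looEvaluate(tab$features, tab$meta$arousalClass, cfgA, nOut = nOut)
      fused <- nestedFuse(evV$predictions, evA$predictions)
      truth <- nestedFuse(tab$meta$valenceClass, tab$meta$arousalClass)
      both <- !is.na(fused) & !is.na(truth)
      evaluation[[paste(method, clf, sep = "_")]] <- list(
        method = method, classifier = clf,
        valenceAccuracy = evV$accuracy, arousalAccuracy = evA$accuracy,
        compositeAccuracy = 100 * mean(fused[both] == truth[both]),
        nValence = evV$nRecords, nArousal = evA$nRecords,
        nComposite = sum(both))
    }
  }
  groupStats <- list()
  for (cond in fluxConditions) {
    res <- tryCatch({
      ft <- cohortFluxTable(cohort, condition = cond)
      compareGroups(ft)
    }, error = function(e) e$message)
    groupStats[[cond]] <- res
    if (is.data.frame(res))
      utils::write.csv(res, file.path(outDir, sprintf("group_ttest_%s.csv", cond)),
                       row.names = FALSE)
  }
  manifest <- list(
    package = "eegconn",
    version = as.character(utils::packageVersion("eegconn")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = if (is.null(inputDir)) unclass(config) else list(inputDir = inputDir),
    methods = methods, classifiers = classifiers, nOut = nOut)
  jsonlite::write_json(list(manifest = manifest, evaluation = evaluation),
                       file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = featureTables, evaluation = evaluation,
                 groupStats = groupStats, outDir = outDir))
}
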