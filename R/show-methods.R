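setMethod("show", "ImuRecording", function(object) {
  cat(sprintf("ImuRecording: %s hand %s, %d samples @ %g Hz\n",
              object@test, object@hand, nrow(object@accel),
              object@sampleRate))
})

setMethod("show", "FctTrial", function(object) {
  cat(sprintf(
    "FctTrial: hand %s, %d samples @ %g Hz, %d target events, radius %g px\n",
    object@hand, nrow(object@markerXY), object@sampleRate,
    nrow(object@targetEvents), object@targetRadius))
})

setMethod("show", "AtaxiaCohort", function(object) {
  s <- object@subjects
  cat(sprintf("AtaxiaCohort: %d subjects (%d ataxic / %d control), %d recordings\n",
              nrow(s), sum(s$group == "ataxic"), sum(s$group == "control"),
              length(object@recordings)))
})

setMethod("show", "AtaxiaFeatureTable", function(object) {
  cat(sprintf("AtaxiaFeatureTable: %d features x %d subjects\n",
              nrow(object), ncol(object)))
  tests <- table(SummarizedExperiment::rowData(object)$test)
  cat("  per test:",
      paste(names(tests), as.integer(tests), sep = "=", collapse = " "), "\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "features")))
  cat("  missing values:", nmiss, "\n")
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf(
    "SelectionReport: %d features, %d runs, alpha %.3g, subsample %.0f%%\n",
    length(object@frequency), object@nIter, object@alpha,
    100 * object@subsampleFraction))
  top <- utils::head(sort(object@frequency, decreasing = TRUE), 5)
  cat("  top frequencies:\n")
  for (nm in names(top)) cat(sprintf("    %-28s %.2f\n", nm, top[[nm]]))
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat(sprintf("EvaluationReport (%s): ACC %.1f%%, Recall %.2f, Precision %.2f, F1 %.2f, MCC %.2f, AUC %.2f\n",
              object@model, 100 * m[["acc"]], m[["recall"]],
              m[["precision"]], m[["f1"]], m[["mcc"]], m[["auc"]]))
  if (!all(is.na(object@ps)))
    cat(sprintf("  severity: Spearman rho %.2f, %d/%d within one level\n",
                object@rho,
                sum(abs(object@level - object@trueLevel) <= 1),
                length(object@level)))
})
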