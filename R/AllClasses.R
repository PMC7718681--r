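#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib ataxiameter, .registration = TRUE
NULL

TESTS  <- c("FCT", "FTT", "FNT", "DDKT")
HANDS  <- c("L", "R")
GROUPS <- c("control", "ataxic")
STAR   <- c("Stability", "Timing", "Accuracy", "Rhythmicity")

#' Tri-axial IMU recording for one hand and one test
#'
#' Holds synchronised accelerometer and gyroscope streams (columns X, Y, Z)
#' for one of the wearable-sensor tests: finger tapping (FTT), finger to nose
#' (FNT) or rapid alternating hand movement (DDKT). Axis units are arbitrary
#' but must be consistent within a cohort; the default sampling rate is 50 Hz.
#'
#' @slot test character, one of "FTT", "FNT", "DDKT".
#' @slot hand character, "L" or "R".
#' @slot sampleRate numeric, Hz.
#' @slot accel T x 3 numeric matrix of linear accelerations.
#' @slot gyro T x 3 numeric matrix of angular velocities.
#' @export
setClass("ImuRecording",
  representation(test = "character", hand = "character",
                 sampleRate = "numeric", accel = "matrix", gyro = "matrix"))

setValidity("ImuRecording", function(object) {
  msg <- character()
  if (!object@test %in% c("FTT", "FNT", "DDKT"))
    msg <- c(msg, "test must be one of FTT, FNT, DDKT")
  if (!object@hand %in% HANDS) msg <- c(msg, "hand must be 'L' or 'R'")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (ncol(object@accel) != 3L || ncol(object@gyro) != 3L)
    msg <- c(msg, "accel and gyro must have 3 columns (X, Y, Z)")
  if (nrow(object@accel) != nrow(object@gyro))
    msg <- c(msg, "accel and gyro must have equal length")
  if (nrow(object@accel) < 2 * object@sampleRate)
    msg <- c(msg, "recording shorter than 2 seconds")
  if (anyNA(object@accel) || anyNA(object@gyro))
    msg <- c(msg, "NaN/NA samples are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct an ImuRecording
#'
#' @param test one of "FTT", "FNT", "DDKT".
#' @param hand "L" or "R".
#' @param accel,gyro T x 3 numeric matrices (axes X, Y, Z).
#' @param sampleRate sampling rate in Hz (default 50).
#' @return An [ImuRecording-class] object.
#' @export
ImuRecording <- function(test, hand, accel, gyro, sampleRate = 50) {
  new("ImuRecording", test = test, hand = hand,
      accel = as.matrix(accel), gyro = as.matrix(gyro),
      sampleRate = sampleRate)
}

#' Finger-chase trial: marker trajectory plus timed target jumps
#'
#' The finger-chase test shows a target disc that jumps to a new screen
#' position each time the subject's projected marker touches it; a complete
#' trial has 20 jumps. The marker is sampled at 30 Hz in screen pixels.
#'
#' @slot hand character, "L" or "R".
#' @slot sampleRate numeric, Hz.
#' @slot markerXY T x 2 numeric matrix of marker pixel positions.
#' @slot targetEvents data.frame with columns `onset_sample` (1-based,
#'   strictly increasing), `x_px`, `y_px`.
#' @slot targetRadius numeric, target disc radius in pixels.
#' @export
setClass("FctTrial",
  representation(hand = "character", sampleRate = "numeric",
                 markerXY = "matrix", targetEvents = "data.frame",
                 targetRadius = "numeric"))

setValidity("FctTrial", function(object) {
  msg <- character()
  ev <- object@targetEvents
  if (!object@hand %in% HANDS) msg <- c(msg, "hand must be 'L' or 'R'")
  if (ncol(object@markerXY) != 2L) msg <- c(msg, "markerXY must be T x 2")
  if (anyNA(object@markerXY)) msg <- c(msg, "NaN/NA marker samples")
  if (!all(c("onset_sample", "x_px", "y_px") %in% names(ev)))
    msg <- c(msg, "targetEvents needs onset_sample, x_px, y_px")
  else {
    if (nrow(ev) < 2) msg <- c(msg, "need at least 2 target events")
    if (nrow(ev) && is.unsorted(ev$onset_sample, strictly = TRUE))
      msg <- c(msg, "onset samples must be strictly increasing")
    if (nrow(ev) && (ev$onset_sample[1] < 1 ||
                     ev$onset_sample[nrow(ev)] > nrow(object@markerXY)))
      msg <- c(msg, "onset samples outside the marker trajectory")
  }
  if (object@targetRadius <= 0) msg <- c(msg, "targetRadius must be > 0")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an FctTrial
#'
#' @param hand "L" or "R".
#' @param markerXY T x 2 matrix of marker pixel positions.
#' @param targetEvents data.frame with onset_sample, x_px, y_px.
#' @param targetRadius target disc radius, pixels.
#' @param sampleRate sampling rate in Hz (default 30).
#' @return An [FctTrial-class] object.
#' @export
FctTrial <- function(hand, markerXY, targetEvents, targetRadius,
                     sampleRate = 30) {
  new("FctTrial", hand = hand, markerXY = as.matrix(markerXY),
      targetEvents = as.data.frame(targetEvents),
      targetRadius = targetRadius, sampleRate = sampleRate)
}

#' A cohort: subject records plus raw recordings
#'
#' @slot subjects data.frame keyed by `subject_id` with columns `group`
#'   ("control"/"ataxic"), `dominant_hand`, `age`, `sara_total`,
#'   `sara_ul_sum`, `sara_ul_mean_rounded`, and optionally the latent
#'   generator severity `severity`.
#' @slot recordings named list of [ImuRecording-class] / [FctTrial-class]
#'   objects keyed `"<subject_id>.<TEST>.<hand>"`; missing recordings are
#'   simply absent (their features become NA).
#' @export
setClass("AtaxiaCohort",
  representation(subjects = "data.frame", recordings = "list"))

setValidity("AtaxiaCohort", function(object) {
  s <- object@subjects
  msg <- character()
  need <- c("subject_id", "group", "sara_total", "sara_ul_sum",
            "sara_ul_mean_rounded")
  if (!all(need %in% names(s)))
    return(paste("subjects must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$subject_id)) msg <- c(msg, "duplicate subject ids")
  if (!all(s$group %in% GROUPS)) msg <- c(msg, "group must be control/ataxic")
  if (any(s$sara_ul_sum > s$sara_total))
    msg <- c(msg, "sara_ul_sum exceeds sara_total")
  if (any(s$sara_ul_sum < 0 | s$sara_ul_sum > 15))
    msg <- c(msg, "sara_ul_sum outside 0-15")
  if (any(s$sara_ul_mean_rounded != round(s$sara_ul_sum / 3)))
    msg <- c(msg, "sara_ul_mean_rounded must equal round(sara_ul_sum/3)")
  keys <- names(object@recordings)
  if (length(object@recordings) && is.null(keys))
    msg <- c(msg, "recordings must be named")
  if (length(msg)) msg else TRUE
})

#' Subjects-by-features table
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] in the
#' orientation Bioconductor uses: the 62 catalog features are rows (with
#' `rowData` columns `feature`, `test`, `signal`, `axis`, `hand`, `star`),
#' subjects are columns (with clinical covariates in `colData`), and the
#' single assay `"features"` holds the extracted values (NA where a
#' recording was missing or a component computation failed).
#'
#' @export
setClass("AtaxiaFeatureTable", contains = "SummarizedExperiment")

setValidity("AtaxiaFeatureTable", function(object) {
  cat62 <- catalogFeatures()
  msg <- character()
  hit <- match(rownames(object), cat62$name)
  if (anyNA(hit) || is.unsorted(hit, strictly = TRUE))
    msg <- c(msg, "rows must be catalog features in canonical order")
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "sara_ul_sum") %in% names(cd)))
    msg <- c(msg, "colData needs group and sara_ul_sum")
  if (length(msg)) msg else TRUE
})

#' Backward-elimination selection report
#'
#' @slot frequency named numeric vector, per-feature selection frequency in
#'   \[0, 1\] across the resampled elimination runs.
#' @slot meanPartialF named numeric, mean partial F statistic of each feature
#'   over the runs in which it appeared in a final model (tie-breaker).
#' @slot alpha significance threshold used for elimination.
#' @slot nIter number of resampled runs.
#' @slot subsampleFraction fraction of rows drawn per run.
#' @slot rankings named list of feature-name character vectors (best first),
#'   one per ranking method ("FBE", "RF", "RELIEF", "LASSO") computed so far.
#' @export
setClass("SelectionReport",
  representation(frequency = "numeric", meanPartialF = "numeric",
                 alpha = "numeric", nIter = "numeric",
                 subsampleFraction = "numeric", rankings = "list"))

setValidity("SelectionReport", function(object) {
  msg <- character()
  if (any(object@frequency < 0 | object@frequency > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  feats <- names(object@frequency)
  for (m in names(object@rankings)) {
    if (!setequal(object@rankings[[m]], feats))
      msg <- c(msg, sprintf("ranking '%s' is not a permutation of features", m))
  }
  if (length(msg)) msg else TRUE
})

#' Leave-one-out evaluation report
#'
#' @slot confusion named numeric (TP, FP, TN, FN) from pooled held-out
#'   predictions ("ataxic" is the positive class).
#' @slot metrics named numeric: acc, recall, precision, f1, mcc, auc.
#' @slot scores per-subject held-out classifier scores (larger = more ataxic).
#' @slot predictedClass per-subject held-out class labels.
#' @slot ps per-subject held-out ridge severity prediction (SARA-UL scale),
#'   NA when severity regression was not run.
#' @slot level integer 0-3 severity bucket of `ps`.
#' @slot trueLevel integer severity bucket of the observed SARA-UL sum.
#' @slot rho Spearman correlation of `ps` against the observed SARA-UL sum.
#' @slot agreement 4 x 4 count matrix, rows = true level, cols = predicted.
#' @slot model classifier name used.
#' @export
setClass("EvaluationReport",
  representation(confusion = "numeric", metrics = "numeric",
                 scores = "numeric", predictedClass = "character",
                 ps = "numeric", level = "numeric", trueLevel = "numeric",
                 rho = "numeric", agreement = "matrix", model = "character"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@confusion)))
    msg <- c(msg, "confusion must name TP, FP, TN, FN")
  m <- object@metrics
  if (any(m[c("acc", "recall", "precision", "f1", "auc")] < -1e-9 |
          m[c("acc", "recall", "precision", "f1", "auc")] > 1 + 1e-9,
          na.rm = TRUE))
    msg <- c(msg, "acc/recall/precision/f1/auc must lie in [0, 1]")
  if (isTRUE(m[["mcc"]] < -1 - 1e-9 || m[["mcc"]] > 1 + 1e-9))
    msg <- c(msg, "mcc must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
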