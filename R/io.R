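#' Write a cohort to disk
#'
#' Canonical on-disk layout: one JSON manifest (`manifest.json`) listing
#' subjects and recordings, one CSV per recording (`t, ax, ay, az, gx, gy,
#' gz` for IMU streams; `t, mx, my` for finger-chase marker trajectories with
#' a `*_targets.csv` sidecar holding `onset_sample, x_px, y_px`).
#'
#' @param cohort an [AtaxiaCohort-class].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "AtaxiaCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- list()
  for (key in names(cohort@recordings)) {
    r <- cohort@recordings[[key]]
    base <- gsub("[^A-Za-z0-9_.-]", "_", key)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (is(r, "ImuRecording")) {
      f <- paste0(base, ".csv")
      tt <- (seq_len(nrow(r@accel)) - 1) / r@sampleRate
      df <- data.frame(t = tt,
                       ax = r@accel[, 1], ay = r@accel[, 2], az = r@accel[, 3],
                       gx = r@gyro[, 1], gy = r@gyro[, 2], gz = r@gyro[, 3])
      utils::write.csv(df, file.path(dir, f), row.names = FALSE)
      recs[[length(recs) + 1]] <- list(
        subject_id = parts[1], test = r@test, hand = r@hand, type = "imu",
        sample_rate = r@sampleRate, file = f)
    } else if (is(r, "FctTrial")) {
      f <- paste0(base, ".csv")
      ft <- paste0(base, "_targets.csv")
      tt <- (seq_len(nrow(r@markerXY)) - 1) / r@sampleRate
      utils::write.csv(data.frame(t = tt, mx = r@markerXY[, 1],
                                  my = r@markerXY[, 2]),
                       file.path(dir, f), row.names = FALSE)
      utils::write.csv(r@targetEvents, file.path(dir, ft), row.names = FALSE)
      recs[[length(recs) + 1]] <- list(
        subject_id = parts[1], test = "FCT", hand = r@hand, type = "fct",
        sample_rate = r@sampleRate, file = f, targets_file = ft,
        target_radius = r@targetRadius)
    } else stop("unknown recording class for key ", key)
  }
  manifest <- list(subjects = cohort@subjects, recordings = recs)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

.read_csv_checked <- function(path, needed) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (!all(needed %in% names(df)))
    stop("malformed CSV '", path, "': missing columns ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  bad <- which(!stats::complete.cases(df[needed]))
  if (length(bad))
    stop("validation error in '", path, "': NaN/NA at data row ", bad[1],
         call. = FALSE)
  df
}

#' Read a cohort from a manifest
#'
#' Loads every recording referenced by the manifest, validating each against
#' its type invariants (equal stream lengths, no NaN, positive sampling
#' rate, strictly increasing target onsets). Subjects with missing
#' recordings are retained; their features are NA downstream.
#'
#' @param manifestPath path to `manifest.json` as written by [writeCohort].
#' @return An [AtaxiaCohort-class].
#' @export
readCohort <- function(manifestPath) {
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  dir <- dirname(manifestPath)
  subjects <- as.data.frame(man$subjects)
  recs <- list()
  rl <- man$recordings
  if (is.data.frame(rl)) rl <- split(rl, seq_len(nrow(rl)))
  for (e in rl) {
    e <- as.list(e)
    key <- paste(e$subject_id, e$test, e$hand, sep = ".")
    if (identical(e$type, "imu")) {
      df <- .read_csv_checked(file.path(dir, e$file),
                              c("t", "ax", "ay", "az", "gx", "gy", "gz"))
      recs[[key]] <- ImuRecording(
        test = e$test, hand = e$hand,
        accel = as.matrix(df[, c("ax", "ay", "az")]),
        gyro = as.matrix(df[, c("gx", "gy", "gz")]),
        sampleRate = e$sample_rate)
    } else if (identical(e$type, "fct")) {
      df <- .read_csv_checked(file.path(dir, e$file), c("t", "mx", "my"))
      ev <- .read_csv_checked(file.path(dir, e$targets_file),
                              c("onset_sample", "x_px", "y_px"))
      recs[[key]] <- FctTrial(
        hand = e$hand, markerXY = as.matrix(df[, c("mx", "my")]),
        targetEvents = ev, targetRadius = e$target_radius,
        sampleRate = e$sample_rate)
    } else stop("unknown recording type '", e$type, "' in manifest")
  }
  new("AtaxiaCohort", subjects = subjects, recordings = recs)
}

#' Extract the full 62-feature table for a cohort
#'
#' Runs the per-test feature recipes over every recording and assembles an
#' [AtaxiaFeatureTable-class] (features as rows, subjects as columns).
#' Missing recordings and failed component computations yield NA values.
#'
#' @param cohort an [AtaxiaCohort-class].
#' @return An [AtaxiaFeatureTable-class].
#' @export
extractFeatures <- function(cohort) {
  stopifnot(is(cohort, "AtaxiaCohort"))
  cat62 <- catalogFeatures()
  subj <- cohort@subjects
  mat <- matrix(NA_real_, nrow = nrow(cat62), ncol = nrow(subj),
                dimnames = list(cat62$name, subj$subject_id))
  for (j in seq_len(nrow(subj))) {
    sid <- subj$subject_id[j]
    for (test in TESTS) for (h in HANDS) {
      key <- paste(sid, test, h, sep = ".")
      r <- cohort@recordings[[key]]
      if (is.null(r)) next
      vals <- if (test == "FCT") extractFctFeatures(r) else
        extractImuFeatures(r)
      mat[names(vals), j] <- vals
    }
  }
  rd <- S4Vectors::DataFrame(cat62[, -1], row.names = cat62$name)
  cd <- S4Vectors::DataFrame(subj[, -1], row.names = subj$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd, colData = cd)
  new("AtaxiaFeatureTable", se)
}

#' @describeIn extractFeatures Feature matrix accessor (subjects x features,
#'   i.e. transposed to the modelling orientation).
#' @param ft an [AtaxiaFeatureTable-class].
#' @export
featureMatrix <- function(ft) t(SummarizedExperiment::assay(ft, "features"))

#' @describeIn extractFeatures Subject covariates (colData) as a data.frame.
#' @export
subjectData <- function(ft) as.data.frame(SummarizedExperiment::colData(ft))

#' @describeIn extractFeatures Feature tags (rowData) as a data.frame.
#' @export
featureInfo <- function(ft) {
  d <- as.data.frame(SummarizedExperiment::rowData(ft))
  d$name <- rownames(d)
  d
}
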