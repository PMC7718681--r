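#' The canonical 62-feature catalog
#'
#' Enumerates every kinematic feature the pipeline extracts, in a fixed,
#' deterministic order, together with its tags. Names follow the grammar
#' `{Feature}_{Test}_{Signal}{Axis}_{Hand}`:
#' \itemize{
#'   \item FCT (finger chase, 14): acceleration alterations `AcAlt`,
#'     reaction time `ReTi` and warping error `DTWEr` on screen axes X and Y,
#'     plus one Fitts'-law kinematic delay `KiDe` per hand (signal `PosXY`).
#'   \item FTT (finger tapping, 8): inter-tap-interval coefficient of
#'     variation `CITI` (taps detected on accelerometer Z) and fuzzy entropy
#'     `FuEn` of accelerometer X, accelerometer Z and gyroscope X, per hand.
#'   \item FNT (finger to nose, 20): resonant frequency `RF` and magnitude
#'     `MR` of the angular acceleration on X/Y/Z and of the linear
#'     acceleration on X; RF only of the linear acceleration on Y and Z.
#'   \item DDKT (alternating hand movement, 20): RF and MR of the angle
#'     (integrated gyroscope) on X/Z, the linear acceleration on X/Z, and
#'     the angular acceleration on Y.
#' }
#' Each feature carries exactly one STAR domain tag (Stability, Timing,
#' Accuracy, Rhythmicity). FNT linear-acceleration features, absent from the
#' published tag table, follow the axis-role rule used for the angular
#' accelerations: X/Z spectral features tag Stability, the Y-axis RF tags
#' Timing.
#'
#' @return A data.frame with 62 rows and columns `name`, `feature`, `test`,
#'   `signal`, `axis`, `hand`, `star`, in canonical order.
#' @examples
#' cat62 <- catalogFeatures()
#' table(cat62$test)
#' @export
catalogFeatures <- function() {
  rows <- list()
  add <- function(feature, test, signal, axis, star) {
    for (h in c("L", "R")) {
      sig <- paste0(signal, axis)
      rows[[length(rows) + 1L]] <<- data.frame(
        name = paste(feature, test, sig, h, sep = "_"),
        feature = feature, test = test, signal = signal,
        axis = axis, hand = h, star = star,
        stringsAsFactors = FALSE)
    }
  }
  ## FCT: 7 per hand
  add("AcAlt", "FCT", "Pos", "X", "Stability")
  add("AcAlt", "FCT", "Pos", "Y", "Stability")
  add("ReTi",  "FCT", "Pos", "X", "Timing")
  add("ReTi",  "FCT", "Pos", "Y", "Timing")
  add("DTWEr", "FCT", "Pos", "X", "Accuracy")
  add("DTWEr", "FCT", "Pos", "Y", "Accuracy")
  add("KiDe",  "FCT", "Pos", "XY", "Timing")
  ## FTT: 4 per hand
  add("CITI", "FTT", "Ac", "Z", "Timing")
  add("FuEn", "FTT", "Ac", "X", "Stability")
  add("FuEn", "FTT", "Ac", "Z", "Rhythmicity")
  add("FuEn", "FTT", "Gy", "X", "Rhythmicity")
  ## FNT: 10 per hand (angular acceleration X/Y/Z RF+MR, linear accel X
  ## RF+MR, linear accel Y/Z RF only)
  add("RF", "FNT", "AAc", "X", "Stability")
  add("MR", "FNT", "AAc", "X", "Stability")
  add("RF", "FNT", "AAc", "Y", "Timing")
  add("MR", "FNT", "AAc", "Y", "Rhythmicity")
  add("RF", "FNT", "AAc", "Z", "Stability")
  add("MR", "FNT", "AAc", "Z", "Stability")
  add("RF", "FNT", "Ac", "X", "Stability")
  add("MR", "FNT", "Ac", "X", "Stability")
  add("RF", "FNT", "Ac", "Y", "Timing")
  add("RF", "FNT", "Ac", "Z", "Stability")
  ## DDKT: 10 per hand
  add("RF", "DDKT", "Ang", "X", "Stability")
  add("MR", "DDKT", "Ang", "X", "Stability")
  add("RF", "DDKT", "Ang", "Z", "Stability")
  add("MR", "DDKT", "Ang", "Z", "Stability")
  add("RF", "DDKT", "Ac", "X", "Stability")
  add("MR", "DDKT", "Ac", "X", "Stability")
  add("RF", "DDKT", "Ac", "Z", "Stability")
  add("MR", "DDKT", "Ac", "Z", "Stability")
  add("RF", "DDKT", "AAc", "Y", "Timing")
  add("MR", "DDKT", "AAc", "Y", "Rhythmicity")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
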