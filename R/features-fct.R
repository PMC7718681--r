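#' Accumulated dynamic-time-warping cost between two sequences
#'
#' Cost of the optimal monotone warping alignment between two 1-D sequences
#' under the recursion
#' `DS(i,j) = |a_i - b_j| + min(DS(i-1,j), DS(i-1,j-1), DS(i,j-1))`
#' with `DS(1,1) = |a_1 - b_1|`; the value returned is `DS(n, m)`. Applied to
#' the (mean-subtracted) marker and target trajectories of the finger-chase
#' test it quantifies overshoot/undershoot displacement in pixels.
#'
#' @param a,b numeric vectors, non-empty.
#' @return A single non-negative number.
#' @examples
#' dtwError(c(0, 1, 2), c(1, 2, 3))  # 2
#' @export
dtwError <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sequence")
  .dtw_cost_cpp(as.numeric(a), as.numeric(b))
}

#' Cross-correlation reaction time
#'
#' The non-negative lag at which shifting the marker trace backwards best
#' aligns it with the piecewise-constant target trace, converted to
#' milliseconds. The correlation at each lag is the normalised
#' cross-correlation over the overlapping segment (cosine similarity), so a
#' pure shift is recovered exactly; lags are searched up to
#' `maxLagFraction` of the record (a lag with almost no overlap would
#' otherwise win on a handful of noisy samples). Both series are demeaned
#' first.
#'
#' @param marker,target numeric vectors of equal length (one screen axis).
#' @param sampleRate sampling rate, Hz.
#' @param maxLagFraction upper lag bound as a fraction of the record length.
#' @return Reaction time in ms.
#' @export
reactionTime <- function(marker, target, sampleRate, maxLagFraction = 0.75) {
  n <- length(marker)
  if (length(target) != n) stop("marker and target must have equal length")
  m <- marker - mean(marker)
  tg <- target - mean(target)
  if (sd(m) == 0 || sd(tg) == 0)
    stop("zero-variance input: correlation undefined")
  maxLag <- max(1L, floor(maxLagFraction * (n - 1L)))
  cc <- vapply(0:maxLag, function(lag) {
    a <- m[(1L + lag):n]; b <- tg[1L:(n - lag)]
    den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    if (den == 0) -Inf else sum(a * b) / den
  }, numeric(1))
  lag <- which.max(cc) - 1L
  lag / sampleRate * 1000
}

.targetTrajectory <- function(trial) {
  ev <- trial@targetEvents
  n <- nrow(trial@markerXY)
  idx <- findInterval(seq_len(n), ev$onset_sample)
  idx[idx == 0L] <- 1L   # hold the first target before its onset
  cbind(ev$x_px[idx], ev$y_px[idx])
}

#' Fitts'-law kinematic delay
#'
#' For each reach (each target jump after the first), the index of difficulty
#' is `ID = log2(di / ra)` where `di` is the Euclidean distance between
#' consecutive target centres and `ra` the target radius; the movement time
#' `MT` is the time from the target's onset to the marker's first entry into
#' the target disc, capped at the inter-event interval when the target jumps
#' away before the marker arrives. Returns the mean of `ID / MT` over
#' reaches, in bits/s. Reaches with `di <= ra` contribute 0 bits.
#'
#' @param trial an [FctTrial-class].
#' @return Kinematic delay in bits/s.
#' @export
kinematicDelay <- function(trial) {
  ev <- trial@targetEvents
  ne <- nrow(ev)
  if (ne < 2) stop("need at least 2 target events")
  fs <- trial@sampleRate
  ra <- trial@targetRadius
  mk <- trial@markerXY
  nT <- nrow(mk)
  rates <- numeric(0)
  for (k in 2:ne) {
    di <- sqrt((ev$x_px[k] - ev$x_px[k - 1])^2 +
               (ev$y_px[k] - ev$y_px[k - 1])^2)
    onset <- ev$onset_sample[k]
    endcap <- if (k < ne) ev$onset_sample[k + 1] - 1L else nT
    seg <- onset:endcap
    d2t <- sqrt((mk[seg, 1] - ev$x_px[k])^2 + (mk[seg, 2] - ev$y_px[k])^2)
    hit <- which(d2t <= ra)
    mt <- if (length(hit)) (hit[1] - 1L) / fs else (endcap - onset) / fs
    mt <- max(mt, 1 / fs)
    id <- if (di > ra) log2(di / ra) else 0
    rates <- c(rates, id / mt)
  }
  mean(rates)
}

#' Acceleration alterations per reach
#'
#' The marker position is lightly smoothed (moving average, default 5
#' samples), double-differenced to an acceleration proxy, and the number of
#' acceleration sign changes is counted within each reach segment; the mean
#' count per reach is returned. Corrective sub-movements and tremor both
#' raise the count.
#'
#' @param x numeric vector, marker position on one screen axis.
#' @param sampleRate sampling rate, Hz (unused by the count itself; kept for
#'   interface symmetry).
#' @param onsets integer vector of reach onset samples; when NULL the whole
#'   series is one reach.
#' @param window moving-average width in samples.
#' @return Mean sign-change count per reach.
#' @export
accelAlterations <- function(x, sampleRate, onsets = NULL, window = 5) {
  n <- length(x)
  if (is.null(onsets)) onsets <- 1L
  xs <- .movavg(as.numeric(x), window)
  bounds <- c(onsets, n + 1L)
  counts <- vapply(seq_along(onsets), function(k) {
    seg <- xs[bounds[k]:min(bounds[k + 1L] - 1L, n)]
    if (length(seg) < 3) return(0)
    acc <- diff(seg, differences = 2)
    s <- sign(acc)
    s <- s[s != 0]
    if (length(s) < 2) 0 else sum(diff(s) != 0)
  }, numeric(1))
  mean(counts)
}

.movavg <- function(x, window) {
  if (window <= 1) return(x)
  out <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  bad <- is.na(out)
  out[bad] <- x[bad]  # keep edges unsmoothed
  out
}

#' Extract the seven finger-chase features for one trial
#'
#' Per screen axis: warping error `DTWEr` (px), reaction time `ReTi` (ms) and
#' the per-trial total of acceleration alterations `AcAlt` (mean per reach
#' times the number of reaches); plus one Fitts'-law kinematic delay `KiDe`
#' (bits/s) per trial. Names follow the feature catalog.
#'
#' @param trial an [FctTrial-class].
#' @return Named numeric vector of length 7.
#' @export
extractFctFeatures <- function(trial) {
  h <- trial@hand
  fs <- trial@sampleRate
  tg <- .targetTrajectory(trial)
  mk <- trial@markerXY
  onsets <- trial@targetEvents$onset_sample
  nre <- length(onsets)
  out <- c()
  for (ax in 1:2) {
    axn <- c("X", "Y")[ax]
    m <- mk[, ax] - mean(mk[, ax])
    tt <- tg[, ax] - mean(tg[, ax])
    out[paste0("DTWEr_FCT_Pos", axn, "_", h)] <- dtwError(m, tt)
    out[paste0("ReTi_FCT_Pos", axn, "_", h)] <-
      reactionTime(mk[, ax], tg[, ax], fs)
    out[paste0("AcAlt_FCT_Pos", axn, "_", h)] <-
      accelAlterations(mk[, ax], fs, onsets) * nre
  }
  out[paste0("KiDe_FCT_PosXY_", h)] <- kinematicDelay(trial)
  out
}
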