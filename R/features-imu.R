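#' Detect table taps from an accelerometer channel
#'
#' Peak detection on the absolute band-passed vertical acceleration:
#' candidate peaks must exceed `madFactor` times the median absolute
#' deviation of `|x|` and be separated by at least `minSeparation` seconds.
#'
#' @param x numeric vector, filtered accelerometer Z channel.
#' @param sampleRate sampling rate, Hz.
#' @param madFactor threshold multiplier on `mad(|x|)` (default 3).
#' @param minSeparation minimum inter-tap separation, s (default 0.15).
#' @return List with `tapTimes` (seconds, strictly increasing) and `iti`
#'   (successive differences).
#' @export
detectTaps <- function(x, sampleRate, madFactor = 3, minSeparation = 0.15) {
  ax <- abs(as.numeric(x))
  thr <- madFactor * stats::mad(ax)
  minDist <- max(1L, round(minSeparation * sampleRate))
  pk <- pracma::findpeaks(ax, minpeakheight = thr,
                          minpeakdistance = minDist)
  if (is.null(pk) || nrow(pk) < 4)
    stop("insufficient taps: fewer than 4 peaks above threshold")
  loc <- sort(pk[, 2])
  tapTimes <- (loc - 1) / sampleRate
  list(tapTimes = tapTimes, iti = diff(tapTimes))
}

#' Coefficient of variation of inter-tap intervals
#'
#' Sample standard deviation of the inter-tap intervals divided by their
#' mean: the variability of the tapping rhythm relative to the tapping rate.
#' Scale-invariant under uniform time rescaling.
#'
#' @param taps list as returned by [detectTaps] (needs `iti` with >= 3
#'   intervals, i.e. >= 4 taps).
#' @return Dimensionless coefficient of variation.
#' @export
citi <- function(taps) {
  iti <- taps$iti
  if (length(iti) < 3) stop("need at least 4 taps (3 intervals)")
  if (any(iti <= 0)) stop("inter-tap intervals must be positive")
  stats::sd(iti) / mean(iti)
}

#' Fuzzy entropy of a time series
#'
#' Template-matching irregularity measure: embed the series in dimension `m`
#' and `m + 1` (templates mean-centred, as in standard fuzzy-entropy
#' practice), measure template distances with the Chebyshev metric, score
#' similarity with the Gaussian-like kernel `exp(-(d/r)^2)`, average over all
#' ordered template pairs excluding self-matches to get `phi^m`, and return
#' `ln phi^m - ln phi^(m+1)` (nat). Lower values indicate more regular,
#' less complex movement.
#'
#' @param y numeric vector, length > m + 1.
#' @param m embedding dimension (default 3).
#' @param r similarity radius; default `0.2 * sd(y)`.
#' @return Fuzzy entropy in nat (non-negative).
#' @export
fuzzyEntropy <- function(y, m = 3, r = 0.2 * stats::sd(y)) {
  y <- as.numeric(y)
  N <- length(y)
  if (N <= m + 1) stop("series too short for embedding dimension m")
  if (!is.finite(r) || r <= 0) stop("radius r must be positive")
  phi <- function(mm) {
    nt <- N - m          # same template count for both dimensions
    X <- sapply(0:(mm - 1), function(k) y[(1:nt) + k])
    X <- X - rowMeans(X) # mean-centre each template
    d <- as.matrix(stats::dist(X, method = "maximum"))
    D <- exp(-(d / r)^2)
    diag(D) <- NA        # exclude self-matches (p != q)
    mean(rowMeans(D, na.rm = TRUE))
  }
  log(phi(m)) - log(phi(m + 1))
}

#' Resonant frequency and its magnitude
#'
#' Single-sided amplitude spectrum (Hann window, zero-padded to the next
#' power of two) of a band-limited signal; the resonant frequency RF is the
#' frequency of the largest bin strictly inside (0, Nyquist) and MR is the
#' amplitude at that bin (input units). Intended for signals already passed
#' through [bandpassSpectral].
#'
#' @param x numeric vector.
#' @param sampleRate sampling rate, Hz.
#' @return List with `rf` (Hz) and `mr` (amplitude, input units).
#' @export
rfMr <- function(x, sampleRate) {
  x <- as.numeric(x)
  n <- length(x)
  if (all(x == 0)) stop("all-zero signal: no spectral peak")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  xw <- x * w
  nfft <- 2^ceiling(log2(n))
  sp <- stats::fft(c(xw, rep(0, nfft - n)))
  half <- 2:(nfft %/% 2)            # exclude DC and Nyquist bins
  amp <- 2 * Mod(sp[half]) / sum(w)
  freq <- (half - 1) * sampleRate / nfft
  i <- which.max(amp)
  list(rf = freq[i], mr = amp[i])
}

#' Extract the IMU feature set for one recording
#'
#' Applies the per-test feature recipe to a wearable-sensor recording:
#' \itemize{
#'   \item FTT: `CITI` from taps detected on accelerometer Z, and fuzzy
#'     entropy of accelerometer X, accelerometer Z and gyroscope X (all
#'     0.3-20 Hz band-passed) -- 4 features.
#'   \item FNT: RF and MR of the angular acceleration (differentiated
#'     gyroscope) on X/Y/Z and of the linear acceleration on X, RF only of
#'     the linear acceleration on Y/Z, each measured after the additional
#'     2-5 Hz band-pass -- 10 features.
#'   \item DDKT: RF and MR of the angle (integrated gyroscope) on X/Z, the
#'     linear acceleration on X/Z and the angular acceleration on Y -- 10
#'     features.
#' }
#' A component failure (e.g. too few taps) yields NA for the affected
#' features rather than an error.
#'
#' @param rec an [ImuRecording-class].
#' @return Named numeric vector (names follow the feature catalog).
#' @export
extractImuFeatures <- function(rec) {
  fs <- rec@sampleRate
  h <- rec@hand
  bp <- function(v) bandpassImu(v, fs)
  sp <- function(v) bandpassSpectral(v, fs)
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  out <- c()
  put <- function(feature, test, sig, value)
    out[paste(feature, test, sig, h, sep = "_")] <<- value

  if (rec@test == "FTT") {
    acz <- bp(rec@accel[, 3])
    put("CITI", "FTT", "AcZ",
        safely(citi(detectTaps(acz, fs))))
    put("FuEn", "FTT", "AcX", safely(fuzzyEntropy(bp(rec@accel[, 1]))))
    put("FuEn", "FTT", "AcZ", safely(fuzzyEntropy(acz)))
    put("FuEn", "FTT", "GyX", safely(fuzzyEntropy(bp(rec@gyro[, 1]))))
  } else if (rec@test == "FNT") {
    for (ax in 1:3) {
      axn <- c("X", "Y", "Z")[ax]
      aac <- safely(sp(angularAcceleration(bp(rec@gyro[, ax]), fs)))
      pk <- if (all(is.na(aac))) list(rf = NA_real_, mr = NA_real_) else
        safely(rfMr(aac, fs))
      if (all(is.na(pk))) pk <- list(rf = NA_real_, mr = NA_real_)
      put("RF", "FNT", paste0("AAc", axn), pk$rf)
      put("MR", "FNT", paste0("AAc", axn), pk$mr)
    }
    for (ax in 1:3) {
      axn <- c("X", "Y", "Z")[ax]
      ac <- safely(sp(bp(rec@accel[, ax])))
      pk <- if (all(is.na(ac))) list(rf = NA_real_, mr = NA_real_) else
        safely(rfMr(ac, fs))
      if (all(is.na(pk))) pk <- list(rf = NA_real_, mr = NA_real_)
      put("RF", "FNT", paste0("Ac", axn), pk$rf)
      if (axn == "X") put("MR", "FNT", "AcX", pk$mr)
    }
  } else if (rec@test == "DDKT") {
    for (axn in c("X", "Z")) {
      ax <- match(axn, c("X", "Y", "Z"))
      ang <- safely(sp(angleFromGyro(bp(rec@gyro[, ax]), fs)))
      pk <- if (all(is.na(ang))) list(rf = NA_real_, mr = NA_real_) else
        safely(rfMr(ang, fs))
      if (all(is.na(pk))) pk <- list(rf = NA_real_, mr = NA_real_)
      put("RF", "DDKT", paste0("Ang", axn), pk$rf)
      put("MR", "DDKT", paste0("Ang", axn), pk$mr)
      ac <- safely(sp(bp(rec@accel[, ax])))
      pk <- if (all(is.na(ac))) list(rf = NA_real_, mr = NA_real_) else
        safely(rfMr(ac, fs))
      if (all(is.na(pk))) pk <- list(rf = NA_real_, mr = NA_real_)
      put("RF", "DDKT", paste0("Ac", axn), pk$rf)
      put("MR", "DDKT", paste0("Ac", axn), pk$mr)
    }
    aacY <- safely(sp(angularAcceleration(bp(rec@gyro[, 2]), fs)))
    pk <- if (all(is.na(aacY))) list(rf = NA_real_, mr = NA_real_) else
      safely(rfMr(aacY, fs))
    if (all(is.na(pk))) pk <- list(rf = NA_real_, mr = NA_real_)
    put("RF", "DDKT", "AAcY", pk$rf)
    put("MR", "DDKT", "AAcY", pk$mr)
  } else stop("unknown test: ", rec@test)
  out
}
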