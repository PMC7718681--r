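#' Zero-phase Butterworth band-pass for raw IMU channels
#'
#' Second-order band-pass (0.3-20 Hz by default) applied forward and backward
#' (zero phase, effective order doubled). The low cut removes drift and the
#' DC component; the high cut restricts the signal to the bandwidth of human
#' movement. Applied per axis, independently.
#'
#' @param x numeric vector, one channel.
#' @param sampleRate sampling rate, Hz.
#' @param low,high band edges, Hz.
#' @param order Butterworth order of the underlying one-pass filter.
#' @return Filtered vector, same length as `x`.
#' @export
bandpassImu <- function(x, sampleRate, low = 0.3, high = 20, order = 2) {
  .bandpass(x, sampleRate, low, high, order)
}

#' Zero-phase Butterworth band-pass for spectral features
#'
#' Sixth-order 2-5 Hz band-pass isolating the oscillation band in which the
#' repetitive finger-to-nose and alternating-hand movements (and pathological
#' tremor) live, ahead of resonant-frequency analysis.
#'
#' @inheritParams bandpassImu
#' @return Filtered vector, same length as `x`.
#' @export
bandpassSpectral <- function(x, sampleRate, low = 2, high = 5, order = 6) {
  .bandpass(x, sampleRate, low, high, order)
}

.bandpass <- function(x, sampleRate, low, high, order) {
  if (!is.numeric(x) || anyNA(x)) stop("signal must be numeric without NA")
  nyq <- sampleRate / 2
  if (low <= 0 || high >= nyq || low >= high)
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
                 low, high, nyq))
  if (length(x) <= 3 * order) stop("signal too short for the filter order")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  .zerophase(bf$b, bf$a, as.numeric(x), sampleRate, low)
}

# Forward-backward filtering with odd-reflection padding and steady-state
# initial conditions (a Butterworth band-pass has H(1) = 0 exactly, so the
# steady-state response to the edge value is zero). This keeps the slow
# high-pass pole's transient out of the data, which plain filtering would
# smear over seconds at a 0.3 Hz corner.
.zerophase <- function(b, a, x, sampleRate, low) {
  n <- length(x)
  k <- max(length(a), length(b)) - 1L
  pad <- min(n - 1L, as.integer(ceiling(3 * sampleRate / low)))
  onePass <- function(v) {
    vp <- c(2 * v[1] - rev(v[2:(pad + 1L)]), v,
            2 * v[length(v)] - rev(v[(length(v) - pad):(length(v) - 1L)]))
    y <- signal::filter(b, a, vp, init.x = rep(vp[1], k),
                        init.y = rep(0, k))
    as.numeric(y)[pad + seq_len(length(v))]
  }
  rev(onePass(rev(onePass(x))))
}

#' Angular acceleration from a gyroscope channel
#'
#' Central finite differences (one-sided at the ends), so a rate signal in
#' unit/s becomes unit/s^2 without phase shift.
#'
#' @param x numeric vector, angular velocity.
#' @param sampleRate sampling rate, Hz.
#' @return Numeric vector of the same length.
#' @export
angularAcceleration <- function(x, sampleRate) {
  if (length(x) < 3) stop("need at least 3 samples")
  pracma::gradient(as.numeric(x), 1 / sampleRate)
}

#' Angle from a gyroscope channel
#'
#' Cumulative trapezoidal integration of a band-passed angular-velocity
#' channel, followed by mean removal to suppress residual drift. The input is
#' assumed to have been high-pass filtered already ([bandpassImu]); otherwise
#' sensor bias integrates into a ramp.
#'
#' @inheritParams angularAcceleration
#' @param demean subtract the mean after integration (default TRUE).
#' @return Numeric vector of the same length (angle in unit * s).
#' @export
angleFromGyro <- function(x, sampleRate, demean = TRUE) {
  ang <- pracma::cumtrapz(as.numeric(x))[, 1] / sampleRate
  if (demean) ang <- ang - mean(ang)
  ang
}
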