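#' Default generator configuration
#'
#' The synthetic cohort emulates the study conditions of the four bedside
#' tests: a 55-subject cohort with 41 ataxic and 14 control subjects by
#' default, graded ataxic severity `s` in \[0.4, 3\] (controls at `s = 0`),
#' and effect-size knobs that are all monotone in `s` in the direction the
#' clinical group differences run: longer reaction delay and movement time,
#' larger overshoot and tremor (finger chase); more variable inter-tap
#' intervals and less complex background movement (tapping); slower, smaller
#' primary oscillation with more secondary-axis leakage (finger-to-nose and
#' alternating-hand). The reaction-delay/movement-time mapping is calibrated
#' so extracted reaction times land near 750 ms for controls and near
#' 1100 ms at `s = 2.5`. Severity maps to the upper-limb SARA sum as
#' `clamp(round(3 s + N(0, 0.5)), 0, 15)`.
#'
#' @param nSubjects cohort size (default 55).
#' @param ataxicFraction fraction of ataxic subjects (default 41/55).
#' @param seed RNG seed.
#' @return Nested list of generator parameters; every `c(a, b)` pair is the
#'   intercept/slope of a linear severity knob `a + b * s`.
#' @export
defaultGeneratorConfig <- function(nSubjects = 55, ataxicFraction = 41 / 55,
                                   seed = 0) {
  list(
    nSubjects = nSubjects, ataxicFraction = ataxicFraction, seed = seed,
    severityRange = c(0.4, 3),
    fct = list(
      sampleRate = 30, nTargets = 20, field = c(1920, 1080),
      targetRadius = 40, margin = 100, minJump = 150,
      reactionDelayMs = c(400, 90),   # ~750 ms ReTi at s=0, ~1100 at s=2.5
      movementTimeS = c(0.70, 0.12),
      overshootGain = c(0.02, 0.12),
      tremorAmpPx = c(1, 8),
      pixelNoiseSd = 1),
    ftt = list(
      sampleRate = 50, duration = 15, meanIti = 0.4,
      itiCv = c(0.05, 0.07),
      spikeAmp = 8,
      backgroundSd = 0.35,
      complexity = c(0.75, -0.18)),   # broadband weight, floor 0.15
    fnt = list(
      sampleRate = 50, duration = 15,
      oscFreqHz = c(3.2, -0.25),
      gyroAmp = c(2.0, -0.45),        # floor 0.3
      accelAmp = c(1.5, -0.30),       # floor 0.3
      secondaryLeak = c(0.15, 0.45),
      whiteSd = 0.05),
    ddkt = list(                      # deliberately milder effects than FTT
      sampleRate = 50, duration = 15,
      oscFreqHz = c(3.0, -0.08),
      gyroAmp = c(1.5, -0.10),
      accelAmp = c(1.2, -0.08),
      secondaryLeak = c(0.20, 0.08),
      whiteSd = 0.30))
}

.knob <- function(ab, s, floor = -Inf) max(ab[1] + ab[2] * s, floor)

.minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Narrowband 2-5 Hz noise with unit sd (tremor / leakage texture).
.narrowband <- function(n, fs) {
  x <- bandpassSpectral(stats::rnorm(n + 4 * fs), fs)[(2 * fs) + seq_len(n)]
  x / max(stats::sd(x), 1e-12)
}

.simulateFct <- function(cfg, s, hand) {
  p <- cfg$fct
  fs <- p$sampleRate
  delay <- .knob(p$reactionDelayMs, s) / 1000
  mt <- .knob(p$movementTimeS, s)
  og <- .knob(p$overshootGain, s)
  lo <- p$margin; hi <- p$field - p$margin
  pos <- c(mean(c(lo, hi[1])), mean(c(lo, hi[2])))
  targets <- matrix(NA_real_, p$nTargets, 2)
  prev <- pos
  for (k in seq_len(p$nTargets)) {
    repeat {
      cand <- c(stats::runif(1, lo, hi[1]), stats::runif(1, lo, hi[2]))
      if (sqrt(sum((cand - prev)^2)) > p$minJump) break
    }
    targets[k, ] <- cand
    prev <- cand
  }
  traj <- list(); onsets <- integer(p$nTargets)
  tcur <- 1L
  for (k in seq_len(p$nTargets)) {
    onsets[k] <- tcur
    dk <- delay * stats::runif(1, 0.9, 1.1)
    mk <- mt * stats::runif(1, 0.9, 1.1)
    nWait <- max(1L, round(dk * fs))
    nMove <- max(4L, round(mk * fs))
    nSettle <- max(2L, round(0.35 * nMove))
    tau <- seq_len(nMove) / nMove
    gain <- .minjerk(tau) * (1 + og)
    settle <- 1 + (og * (1 + cos(pi * seq_len(nSettle) / nSettle)) / 2)
    prof <- c(rep(0, nWait), gain, settle)
    dirv <- targets[k, ] - pos
    seg <- cbind(pos[1] + dirv[1] * prof, pos[2] + dirv[2] * prof)
    traj[[k]] <- seg
    pos <- seg[nrow(seg), ]
    tcur <- tcur + nrow(seg)
  }
  marker <- do.call(rbind, traj)
  n <- nrow(marker)
  trem <- .knob(p$tremorAmpPx, s)
  marker[, 1] <- marker[, 1] + trem * .narrowband(n, fs) +
    stats::rnorm(n, sd = p$pixelNoiseSd)
  marker[, 2] <- marker[, 2] + trem * .narrowband(n, fs) +
    stats::rnorm(n, sd = p$pixelNoiseSd)
  FctTrial(hand = hand, markerXY = marker,
           targetEvents = data.frame(onset_sample = onsets,
                                     x_px = targets[, 1],
                                     y_px = targets[, 2]),
           targetRadius = p$targetRadius, sampleRate = fs)
}

# Background movement texture whose complexity (broadband weight) falls
# with severity: w * white noise + (1 - w) * slow smooth oscillation.
.texture <- function(n, fs, w, sd) {
  tt <- seq_len(n) / fs
  slow <- sin(2 * pi * 1.1 * tt + stats::runif(1, 0, 2 * pi)) +
    0.4 * sin(2 * pi * 2.3 * tt + stats::runif(1, 0, 2 * pi))
  sd * (w * stats::rnorm(n) + (1 - w) * slow / stats::sd(slow))
}

.simulateFtt <- function(cfg, s, hand) {
  p <- cfg$ftt
  fs <- p$sampleRate
  n <- p$duration * fs
  cv <- .knob(p$itiCv, s)
  w <- .knob(p$complexity, s, floor = 0.15)
  tt <- 0.5
  taps <- c()
  while (tt < p$duration - 0.5) {
    taps <- c(taps, tt)
    tt <- tt + max(0.18, p$meanIti * (1 + cv * stats::rnorm(1)))
  }
  spike <- function() {
    z <- numeric(n)
    for (tp in taps) {
      i0 <- round(tp * fs)
      width <- 6L   # ~50 ms Gaussian contact transient, band-limited
      idx <- (i0 - width):(i0 + width)
      idx <- idx[idx >= 1 & idx <= n]
      z[idx] <- z[idx] + p$spikeAmp * stats::runif(1, 0.8, 1.2) *
        exp(-((idx - i0)^2) / (2 * 2.5^2))
    }
    z
  }
  accel <- cbind(.texture(n, fs, w, p$backgroundSd * 2),
                 .texture(n, fs, w, p$backgroundSd),
                 .texture(n, fs, w, p$backgroundSd) + spike())
  gyro <- cbind(.texture(n, fs, w, p$backgroundSd),
                .texture(n, fs, w, p$backgroundSd * 0.5),
                .texture(n, fs, w, p$backgroundSd * 0.5))
  ImuRecording("FTT", hand, accel, gyro, fs)
}

.simulateOscTest <- function(p, test, s, hand) {
  fs <- p$sampleRate
  n <- p$duration * fs
  tt <- seq_len(n) / fs
  f <- .knob(p$oscFreqHz, s, floor = 2.1)
  gA <- .knob(p$gyroAmp, s, floor = 0.3)
  aA <- .knob(p$accelAmp, s, floor = 0.3)
  leak <- .knob(p$secondaryLeak, s)
  ph <- stats::runif(6, 0, 2 * pi)
  osc <- function(amp, k) amp * sin(2 * pi * f * tt + ph[k]) +
    0.1 * amp * sin(2 * pi * 2 * f * tt + ph[k] + 1)
  wob <- function() leak * .narrowband(n, fs)
  wn <- function() stats::rnorm(n, sd = p$whiteSd)
  ## primary oscillation: gyro Y and accel X for the reach-like movement,
  ## gyro X (forearm roll) and accel X for the alternating-hand movement
  if (test == "FNT") {
    gyro <- cbind(wob() + wn(), osc(gA, 1) + wn(), wob() + wn())
  } else {
    gyro <- cbind(osc(gA, 1) + wn(), wob() + wn(), wob() + wn())
  }
  accel <- cbind(osc(aA, 4) + wn(), wob() + wn(), wob() + wn())
  ImuRecording(test, hand, accel, gyro, fs)
}

#' Simulate one subject's full recording set
#'
#' Generates the four tests for both hands at severity `s` plus the subject
#' record (SARA scores derived from `s`). Uses the current RNG state; seed
#' upstream for reproducibility.
#'
#' @param cfg configuration from [defaultGeneratorConfig].
#' @param s severity in \[0, 3\] (0 = control-like).
#' @param subjectId id string (must not contain ".").
#' @param group "control" or "ataxic".
#' @return List with `subject` (one-row data.frame) and `recordings`
#'   (named list keyed `<id>.<TEST>.<hand>`).
#' @export
simulateSubject <- function(cfg, s, subjectId, group) {
  recs <- list()
  for (h in HANDS) {
    recs[[paste(subjectId, "FCT", h, sep = ".")]] <- .simulateFct(cfg, s, h)
    recs[[paste(subjectId, "FTT", h, sep = ".")]] <- .simulateFtt(cfg, s, h)
    recs[[paste(subjectId, "FNT", h, sep = ".")]] <-
      .simulateOscTest(cfg$fnt, "FNT", s, h)
    recs[[paste(subjectId, "DDKT", h, sep = ".")]] <-
      .simulateOscTest(cfg$ddkt, "DDKT", s, h)
  }
  ul <- min(max(round(3 * s + stats::rnorm(1, 0, 0.5)), 0), 15)
  total <- ul + min(max(round(4 * s + stats::rnorm(1, 0, 1)), 0), 25)
  subject <- data.frame(
    subject_id = subjectId, group = group,
    dominant_hand = sample(c("L", "R"), 1, prob = c(0.15, 0.85)),
    age = round(stats::runif(1, 25, 78)),
    sara_total = total, sara_ul_sum = ul,
    sara_ul_mean_rounded = round(ul / 3),
    severity = s, stringsAsFactors = FALSE)
  list(subject = subject, recordings = recs)
}

#' Simulate a full cohort in memory
#'
#' Draws `round(nSubjects * ataxicFraction)` ataxic subjects with severities
#' uniform over the configured range and the remainder as controls at
#' `s = 0`, then generates all recordings. Deterministic given `cfg$seed`.
#'
#' @param cfg configuration from [defaultGeneratorConfig].
#' @return An [AtaxiaCohort-class] whose `subjects` include the latent
#'   `severity` column as ground truth.
#' @export
simulateCohortData <- function(cfg = defaultGeneratorConfig()) {
  set.seed(cfg$seed)
  n <- cfg$nSubjects
  nAtaxic <- round(n * cfg$ataxicFraction)
  groups <- c(rep("ataxic", nAtaxic), rep("control", n - nAtaxic))
  sev <- c(stats::runif(nAtaxic, cfg$severityRange[1], cfg$severityRange[2]),
           rep(0, n - nAtaxic))
  subjects <- list(); recs <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    sim <- simulateSubject(cfg, sev[i], sid, groups[i])
    subjects[[i]] <- sim$subject
    recs <- c(recs, sim$recordings)
  }
  new("AtaxiaCohort", subjects = do.call(rbind, subjects),
      recordings = recs)
}

#' Simulate a cohort and write it to disk
#'
#' @inheritParams simulateCohortData
#' @param dir output directory for the manifest and recording CSVs.
#' @return The [AtaxiaCohort-class], invisibly; the manifest lands at
#'   `file.path(dir, "manifest.json")`.
#' @export
simulateCohort <- function(cfg = defaultGeneratorConfig(), dir) {
  cohort <- simulateCohortData(cfg)
  writeCohort(cohort, dir)
  invisible(cohort)
}

#' Read generator configuration from YAML
#'
#' Values present in the file override the defaults; anything omitted keeps
#' its default. Severity knobs are `[intercept, slope]` pairs.
#'
#' @param path YAML file.
#' @return Configuration list as from [defaultGeneratorConfig].
#' @export
readGeneratorConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- defaultGeneratorConfig()
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge2(cfg, usr)
}
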