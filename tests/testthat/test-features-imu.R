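spikeTrain <- function(n, fs, times, amp = 8) {
  z <- numeric(n)
  z[round(times * fs) + 1] <- amp
  z
}

test_that("tap detection finds a regular spike train", {
  fs <- 50; n <- 15 * fs
  times <- 0.5 + 0.4 * (0:19)
  z <- spikeTrain(n, fs, times)
  taps <- detectTaps(z, fs)
  expect_length(taps$tapTimes, 20)
  expect_equal(taps$iti, rep(0.4, 19), tolerance = 1e-9)
  # sub-threshold noise does not add or remove taps: bounded noise whose
  # amplitude stays below 3*mad(|signal|)
  set.seed(1)
  noise <- runif(n, -0.05, 0.05)
  taps2 <- detectTaps(z + noise, fs)
  expect_length(taps2$tapTimes, 20)
  expect_error(detectTaps(rep(0, n), fs), "insufficient taps")
})

test_that("CITI matches hand arithmetic and is scale invariant", {
  expect_equal(citi(list(iti = rep(0.4, 10))), 0)
  expect_equal(citi(list(iti = c(0.5, 0.5, 1.0))),
               sd(c(0.5, 0.5, 1.0)) / mean(c(0.5, 0.5, 1.0)))
  expect_equal(round(citi(list(iti = c(0.5, 0.5, 1.0))), 3), 0.433)
  expect_equal(citi(list(iti = 3 * c(0.4, 0.5, 0.6))),
               citi(list(iti = c(0.4, 0.5, 0.6))))
})

test_that("fuzzy entropy matches the double-loop oracle on short series", {
  for (seed in 0:19) {
    set.seed(seed)
    y <- rnorm(10)
    expect_equal(fuzzyEntropy(y), oracleFuzzyEntropy(y), tolerance = 1e-12)
  }
})

test_that("fuzzy entropy behaves like an irregularity measure", {
  expect_equal(fuzzyEntropy(rep(2, 50), r = 0.1), 0)
  set.seed(0)
  for (seed in 0:9) {
    set.seed(seed)
    noise <- rnorm(750)
    tt <- seq_len(750) / 50
    tone <- sin(2 * pi * 2 * tt); tone <- tone / sd(tone)
    expect_gt(fuzzyEntropy(noise), fuzzyEntropy(tone))
  }
  # affine invariance when r tracks the scale
  set.seed(3)
  y <- rnorm(100)
  expect_equal(fuzzyEntropy(5 * y + 2), fuzzyEntropy(y), tolerance = 1e-9)
  expect_gte(fuzzyEntropy(rnorm(200)), 0)
  expect_error(fuzzyEntropy(rnorm(3), m = 3), "too short")
})

test_that("spectral peak recovers tone frequency and scales with amplitude", {
  fs <- 50
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  binw <- fs / 512   # 500 samples zero-padded to 512
  for (f in seq(2, 5, by = 0.25)) {
    pk <- rfMr(sin(2 * pi * f * tt), fs)
    expect_lte(abs(pk$rf - f), binw + 1e-9)
  }
  p1 <- rfMr(2 * sin(2 * pi * 3 * tt), fs)
  p2 <- rfMr(4 * sin(2 * pi * 3 * tt), fs)
  expect_equal(p2$mr / p1$mr, 2, tolerance = 1e-9)
  expect_equal(p1$rf, p2$rf)
  # stronger of two tones wins
  two <- 2 * sin(2 * pi * 2.5 * tt) + 1 * sin(2 * pi * 4 * tt)
  expect_lte(abs(rfMr(two, fs)$rf - 2.5), binw + 1e-9)
  expect_error(rfMr(rep(0, 100), fs), "all-zero")
})

test_that("per-test IMU extraction yields the catalog feature counts", {
  co <- tinyCohort()
  keys <- names(co@recordings)
  ftt <- extractImuFeatures(co@recordings[[grep("FTT", keys)[1]]])
  fnt <- extractImuFeatures(co@recordings[[grep("FNT", keys)[1]]])
  ddkt <- extractImuFeatures(co@recordings[[grep("DDKT", keys)[1]]])
  expect_length(ftt, 4)
  expect_length(fnt, 10)
  expect_length(ddkt, 10)
  cat62 <- catalogFeatures()
  expect_true(all(c(names(ftt), names(fnt), names(ddkt)) %in% cat62$name))
  rfs <- c(fnt[grep("^RF", names(fnt))], ddkt[grep("^RF", names(ddkt))])
  expect_true(all(rfs > 0 & rfs < 25, na.rm = TRUE))  # inside (0, Nyquist)
})
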