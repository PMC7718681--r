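test_that("warping error matches frozen hand cases", {
  expect_equal(dtwError(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(dtwError(c(0, 1, 2), c(1, 2, 3)), 2)
  expect_equal(dtwError(c(0, 0, 0), c(1, 1, 1)), 3)
  expect_error(dtwError(numeric(0), 1), "empty")
})

test_that("warping error equals exhaustive path enumeration on a grid", {
  seqs <- c(gridSequences(1), gridSequences(2), gridSequences(3))
  for (a in seqs) for (b in seqs) {
    expect_equal(dtwError(a, b), oracleDtw(a, b))
  }
  set.seed(42)
  for (rep in 1:200) {
    a <- sample(0:2, sample(4:6, 1), replace = TRUE)
    b <- sample(0:2, sample(4:6, 1), replace = TRUE)
    expect_equal(dtwError(a, b), oracleDtw(a, b))
  }
})

test_that("warping error is symmetric", {
  set.seed(7)
  for (rep in 1:20) {
    a <- rnorm(8); b <- rnorm(11)
    expect_equal(dtwError(a, b), dtwError(b, a))
  }
})

test_that("reaction time recovers pure shifts exactly", {
  fs <- 30
  set.seed(5)
  onset <- sort(sample(10:280, 8))
  target <- rep(0, 300)
  for (o in onset) target[o:300] <- rnorm(1, sd = 100)
  for (shift in c(0, 3, 6, 15, 30)) {
    marker <- c(rep(target[1], shift), target[1:(300 - shift)])
    rt <- reactionTime(marker, target, fs)
    expect_equal(rt, shift / fs * 1000, tolerance = 1e-9)
  }
  # the documented example: 6 samples at 30 Hz is 200 ms
  marker <- c(rep(target[1], 6), target[1:294])
  expect_equal(reactionTime(marker, target, fs), 200)
  expect_error(reactionTime(rep(1, 100), target[1:100], fs),
               "zero-variance")
})

test_that("kinematic delay follows Fitts' law arithmetic", {
  # two events 80 px apart, radius 10, entry after exactly 1.5 s at 30 Hz
  fs <- 30
  n <- 120
  marker <- matrix(c(rep(0, n), rep(0, n)), ncol = 2)
  onset2 <- 31L
  entry <- onset2 + 45L   # 1.5 s later
  marker[entry:n, 1] <- 80
  ev <- data.frame(onset_sample = c(1L, onset2), x_px = c(0, 80),
                   y_px = c(0, 0))
  tr <- FctTrial("L", marker, ev, targetRadius = 10, sampleRate = fs)
  expect_equal(kinematicDelay(tr), log2(80 / 10) / 1.5)   # 3 bits / 1.5 s
  # doubling MT halves KiDe
  marker2 <- matrix(0, 2 * n, 2)
  marker2[(onset2 + 90):(2 * n), 1] <- 80
  tr2 <- FctTrial("L", marker2, ev, targetRadius = 10, sampleRate = fs)
  expect_equal(kinematicDelay(tr2), kinematicDelay(tr) / 2)
  # di = ra contributes zero information
  ev3 <- data.frame(onset_sample = c(1L, onset2), x_px = c(0, 10),
                    y_px = c(0, 0))
  marker3 <- marker; marker3[entry:n, 1] <- 10
  tr3 <- FctTrial("L", marker3, ev3, targetRadius = 10, sampleRate = fs)
  expect_equal(kinematicDelay(tr3), 0)
})

test_that("acceleration alterations count sign changes", {
  fs <- 30
  expect_equal(accelAlterations(seq(0, 99) * 2, fs, window = 1), 0)
  # minimum-jerk reach: smooth profile, count equals the direct
  # second-difference oracle
  tau <- seq(0, 1, length.out = 60)
  mj <- 100 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  oracleCount <- function(x) {
    s <- sign(diff(x, differences = 2)); s <- s[s != 0]
    sum(diff(s) != 0)
  }
  expect_equal(accelAlterations(mj, fs, window = 1), oracleCount(mj))
  expect_lte(accelAlterations(mj, fs, window = 1), 2)
  # added tremor strictly increases the count
  trem <- mj + 3 * sin(2 * pi * 8 * seq_along(mj) / fs)
  expect_gt(accelAlterations(trem, fs), accelAlterations(mj, fs))
})

test_that("FCT extraction emits the seven catalog features", {
  co <- tinyCohort()
  tr <- co@recordings[[grep("FCT", names(co@recordings))[1]]]
  vals <- extractFctFeatures(tr)
  expect_length(vals, 7)
  cat62 <- catalogFeatures()
  expect_true(all(names(vals) %in% cat62$name))
  expect_true(all(vals[grep("DTWEr|ReTi|AcAlt", names(vals))] >= 0))
  expect_gt(vals[grep("KiDe", names(vals))], 0)
})
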