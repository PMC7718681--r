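simTable <- function(n = 200, pNoise = 9, seed = 0, coef = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * (pNoise + 1)), n,
              dimnames = list(NULL, paste0("f", 1:(pNoise + 1))))
  y <- coef * X[, 1] + rnorm(n)
  list(X = X, y = y)
}

test_that("a strongly informative feature survives almost every run", {
  d <- simTable()
  set.seed(0)
  surv <- replicate(100, "f1" %in% fbeOnce(d$X, d$y))
  expect_gte(sum(surv), 95)
})

test_that("null data yields roughly alpha-level survivors", {
  set.seed(1)
  X <- matrix(rnorm(200 * 20), 200, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rnorm(200)
  set.seed(2)
  counts <- replicate(50, length(fbeOnce(X, y)))
  # expected false-survivor count is around alpha * p; allow generous slack
  expect_lt(mean(counts), 0.05 * 20 * 3 + 1)
})

test_that("alpha limits behave as the elimination rule implies", {
  d <- simTable(n = 50, pNoise = 4)
  set.seed(3)
  expect_setequal(fbeOnce(d$X, d$y, alpha = 1), colnames(d$X))
  set.seed(3)
  Xnull <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  expect_length(fbeOnce(Xnull, rnorm(50), alpha = 1e-12), 0)
  # a single feature significant by construction survives
  set.seed(4)
  x1 <- matrix(rnorm(100), dimnames = list(NULL, "only"))
  expect_equal(as.character(fbeOnce(x1, 3 * x1[, 1] + rnorm(100, sd = 0.5))),
               "only")
})

test_that("selection frequency is deterministic and bounded", {
  d <- simTable(n = 80, pNoise = 5)
  r1 <- selectionFrequency(d$X, d$y, nIter = 10, seed = 7)
  r2 <- selectionFrequency(d$X, d$y, nIter = 10, seed = 7)
  expect_identical(r1@frequency, r2@frequency)
  expect_identical(r1@rankings$FBE, r2@rankings$FBE)
  expect_true(all(r1@frequency >= 0 & r1@frequency <= 1))
  rOne <- selectionFrequency(d$X, d$y, nIter = 1, seed = 7)
  expect_true(all(rOne@frequency %in% c(0, 1)))
})

test_that("a collinear duplicate splits survivals rather than adding", {
  d <- simTable(n = 150, pNoise = 5, coef = 1.5)
  rOrig <- selectionFrequency(d$X, d$y, nIter = 40, seed = 5)
  Xdup <- cbind(d$X, f1_copy = d$X[, 1])
  rDup <- selectionFrequency(Xdup, d$y, nIter = 40, seed = 5)
  combined <- rDup@frequency[["f1"]] + rDup@frequency[["f1_copy"]]
  expect_lte(combined, rOrig@frequency[["f1"]] + 0.05)
})

test_that("every ranking method puts a perfectly separating feature first", {
  set.seed(6)
  n <- 60
  labels <- rep(c("control", "ataxic"), each = n / 2)
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 3] <- ifelse(labels == "ataxic", 6, 0) + rnorm(n, sd = 0.2)
  y <- ifelse(labels == "ataxic", 8, 0) + rnorm(n)
  for (m in c("FBE", "RF", "RELIEF", "LASSO")) {
    rk <- rankFeatures(m, X, y = y, labels = labels, seed = 1, nIter = 20)
    expect_equal(rk[1], "f3")
    expect_setequal(rk, colnames(X))
  }
  expect_error(rankFeatures("XGB", X, y = y, labels = labels), "unknown")
})
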