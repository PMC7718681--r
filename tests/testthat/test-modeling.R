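gaussCohort <- function(n = 40, d = 6, seed = 1) {
  set.seed(seed)
  labels <- rep(c("ataxic", "control"), each = n / 2)
  X <- matrix(rnorm(n * 2), n, dimnames = list(paste0("s", 1:n), c("a", "b")))
  X[labels == "ataxic", 1] <- X[labels == "ataxic", 1] + d
  list(X = X, labels = labels)
}

test_that("confusion metrics match hand arithmetic", {
  m <- metricsFromConfusion(2, 1, 3, 0)
  expect_equal(m[["precision"]], 2 / 3)
  expect_equal(m[["recall"]], 1)
  expect_equal(m[["f1"]], 0.8)
  expect_equal(m[["mcc"]], 6 / sqrt(72))
  expect_equal(round(m[["mcc"]], 3), 0.707)
  all1 <- metricsFromConfusion(10, 0, 5, 0, scores = c(rep(1, 10), rep(0, 5)),
                               labels = rep(c("ataxic", "control"), c(10, 5)))
  expect_equal(unname(all1[c("acc", "recall", "precision", "f1", "mcc",
                             "auc")]), rep(1, 6))
  # the published operating point: 53 of 55 correct
  op <- metricsFromConfusion(40, 1, 13, 1)
  expect_equal(round(100 * op[["acc"]], 1), 96.4)
  expect_message(metricsFromConfusion(0, 0, 5, 0), "denominator")
})

test_that("well-separated classes are perfectly classified by all models", {
  g <- gaussCohort()
  for (m in c("QDA", "LD", "SVM", "KNN")) {
    r <- looClassify(g$X, g$labels, model = m)
    expect_equal(r$metrics[["acc"]], 1)
    expect_equal(r$metrics[["mcc"]], 1)
    expect_equal(r$metrics[["auc"]], 1)
  }
})

test_that("QDA implementation agrees with the reference fit on easy data", {
  g <- gaussCohort(n = 60, d = 3, seed = 2)
  fit <- ataxiameter:::.qdaFit(g$X, g$labels, shrink = 0)
  ref <- MASS::qda(g$X, grouping = factor(g$labels))
  ours <- apply(g$X, 1, function(x) {
    ll <- ataxiameter:::.qdaLogLik(fit, x)
    names(ll)[which.max(ll)]
  })
  theirs <- as.character(predict(ref, g$X)$class)
  expect_equal(unname(ours), theirs)
})

test_that("shuffled labels fall to the class-prior baseline", {
  set.seed(0)
  n <- 30
  X <- matrix(rnorm(n * 2), n, dimnames = list(paste0("s", 1:n), c("a", "b")))
  labels <- rep(c("ataxic", "control"), each = n / 2)
  accs <- replicate(60, {
    looClassify(X, sample(labels), model = "LD")$metrics[["acc"]]
  })
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("LOO reports are invariant to subject ordering", {
  g <- gaussCohort(n = 30, d = 2.5, seed = 3)
  r1 <- looClassify(g$X, g$labels, model = "QDA")
  perm <- sample(seq_len(30))
  r2 <- looClassify(g$X[perm, ], g$labels[perm], model = "QDA")
  expect_equal(r1$confusion, r2$confusion)
  expect_equal(r1$metrics, r2$metrics)
  expect_equal(r2$scores[names(r1$scores)], r1$scores)
})

test_that("ridge severity recovers a noiseless linear response", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(paste0("s", 1:40), NULL))
  colnames(X) <- c("u", "v", "w")
  y <- 2 + X %*% c(1, -2, 0.5)
  r <- looSeverity(X, as.numeric(y))
  expect_equal(r$rho, 1)
  expect_error(looSeverity(X, rep(3, 40)), "zero-variance")
})

test_that("severity buckets follow the printed thresholds", {
  expect_equal(bucketSeverity(c(0, 3.999, 4, 6.9, 7, 9.99, 10, 14)),
               c(0, 0, 1, 1, 2, 2, 3, 3))
  set.seed(5)
  lv <- bucketSeverity(runif(50, 0, 14))
  tv <- bucketSeverity(runif(50, 0, 14))
  A <- ataxiameter:::.agreementMatrix(tv, lv)
  expect_equal(dim(A), c(4L, 4L))
  rs <- rowSums(A)
  norm <- A / ifelse(rs == 0, 1, rs)
  expect_true(all(abs(rowSums(norm)[rs > 0] - 1) < 1e-12))
  expect_equal(sum(A), 50)
})

test_that("evaluation report metrics are consistent with stored confusion", {
  ft <- features100()
  rep_ <- memo("eval100", evaluateCohort(ft, topk = 22, model = "QDA",
                                         nIter = 100, seed = 1))
  cm <- rep_@confusion
  re <- metricsFromConfusion(cm[["TP"]], cm[["FP"]], cm[["TN"]], cm[["FN"]])
  expect_equal(rep_@metrics[names(re)], re)
  expect_equal(as.numeric(rep_@level), as.numeric(bucketSeverity(rep_@ps)))
  expect_equal(sum(rep_@agreement), length(rep_@ps))
})

test_that("test-group evaluation covers G1-G6 and matches the full model", {
  ft <- features100()
  # topk = 10 so feature selection is active in every group: G1 has only
  # 22 features in total, and "top 22 of 22" would disable selection there
  tg <- memo("tg100", evaluateTestGroups(
    ft, groups = list(G1 = c("FCT", "FTT"), G3 = c("FCT", "DDKT"),
                      all = c("FCT", "FTT", "FNT", "DDKT")),
    topk = 10, nIter = 40, seed = 1))
  full <- evaluateCohort(ft, topk = 10, model = "QDA", nIter = 40, seed = 1)
  allRow <- tg[tg$group == "all", ]
  expect_equal(allRow$acc, full@metrics[["acc"]])
  expect_equal(allRow$rho, full@rho)
  # the tapping test carries more discriminative signal than the
  # alternating-hand test in the generator, as in the clinical ordering
  g1 <- tg[tg$group == "G1", ]; g3 <- tg[tg$group == "G3", ]
  expect_gte(g1$acc, g3$acc)
  expect_gte(g1$auc, g3$auc)
  expect_error(evaluateTestGroups(ft, groups = list(bad = "XYZ")),
               "no features")
})

test_that("STAR composition percentages sum to 100", {
  ft <- features100()
  info <- featureInfo(ft)
  pct <- starComposition(ft, info$name[info$test %in% c("FCT", "FTT")])
  expect_equal(sum(pct), 100)
  expect_gt(pct[["Accuracy"]], 0)   # FCT contributes accuracy features
})
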