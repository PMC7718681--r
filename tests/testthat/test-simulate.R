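test_that("default cohort reproduces the study group sizes", {
  cfg <- defaultGeneratorConfig()   # 55 subjects, ataxic fraction 41/55
  co <- memo("c55small", simulateCohortData(cfg))
  s <- co@subjects
  expect_equal(sum(s$group == "ataxic"), 41)
  expect_equal(sum(s$group == "control"), 14)
  expect_true(all(s$sara_ul_sum <= s$sara_total))
  expect_true(all(s$sara_ul_mean_rounded == round(s$sara_ul_sum / 3)))
  expect_true(all(s$severity[s$group == "control"] == 0))
  expect_equal(length(co@recordings), 55 * 8)
})

test_that("generation is deterministic given the seed", {
  cfg <- defaultGeneratorConfig(nSubjects = 2, seed = 123)
  a <- simulateCohortData(cfg)
  b <- simulateCohortData(cfg)
  expect_identical(a@subjects, b@subjects)
  k <- names(a@recordings)[1]
  expect_identical(a@recordings[[k]]@markerXY, b@recordings[[k]]@markerXY)
  k2 <- grep("FNT", names(a@recordings))[1]
  expect_identical(a@recordings[[k2]]@gyro, b@recordings[[k2]]@gyro)
})

test_that("simulated recordings satisfy the reader's invariants on disk", {
  co <- tinyCohort()
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(file.path(dir, "manifest.json"))
  expect_s4_class(back, "AtaxiaCohort")
  expect_true(validObject(back))
  for (r in back@recordings) expect_true(validObject(r))
  fct <- back@recordings[[grep("FCT", names(back@recordings))[1]]]
  expect_equal(nrow(fct@targetEvents), 20)
})

test_that("feature families respond monotonically to severity", {
  ft <- features100()
  X <- featureMatrix(ft)
  s <- subjectData(ft)$severity
  expectDir <- c(KiDe_FCT_PosXY_L = -1, KiDe_FCT_PosXY_R = -1,
                 ReTi_FCT_PosX_L = 1, ReTi_FCT_PosY_R = 1,
                 DTWEr_FCT_PosX_L = 1, DTWEr_FCT_PosY_R = 1,
                 AcAlt_FCT_PosX_L = 1, AcAlt_FCT_PosY_R = 1,
                 FuEn_FTT_AcX_L = -1, FuEn_FTT_AcZ_R = -1,
                 FuEn_FTT_GyX_R = -1,
                 MR_FNT_AAcY_L = -1, MR_FNT_AAcY_R = -1,
                 CITI_FTT_AcZ_L = 1, CITI_FTT_AcZ_R = 1)
  for (f in names(expectDir)) {
    rho <- cor(X[, f], s, method = "spearman", use = "complete.obs")
    expect_gte(rho * expectDir[[f]], 0.5)
  }
})

test_that("reaction time lands near the clinical anchor means", {
  ft <- features100()
  X <- featureMatrix(ft)
  sdat <- subjectData(ft)
  ctrl <- sdat$group == "control"
  severe <- sdat$severity > 2
  reti <- rowMeans(X[, c("ReTi_FCT_PosX_L", "ReTi_FCT_PosX_R",
                         "ReTi_FCT_PosY_L", "ReTi_FCT_PosY_R")])
  expect_lt(abs(mean(reti[ctrl]) - 750), 150)
  expect_lt(abs(mean(reti[severe]) - 1100), 220)
  expect_gt(mean(reti[severe]) - mean(reti[ctrl]), 200)
})

test_that("ground-truth severity is recoverable within one bucket", {
  ft <- features100()
  rep_ <- memo("eval100", evaluateCohort(ft, topk = 22, model = "QDA",
                                         nIter = 100, seed = 1))
  agree <- mean(abs(rep_@level - rep_@trueLevel) <= 1)
  expect_gte(agree, 0.9)
})
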