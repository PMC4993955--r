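test_that("cohort generation is deterministic given (config, seed)", {
  cfg <- simConfig(nParticipants = 150)
  a <- generateCohort(cfg, seed = 1)
  b <- generateCohort(cfg, seed = 1)
  expect_identical(a, b)
  d <- generateCohort(cfg, seed = 2)
  expect_false(identical(a$knees$severity, d$knees$severity))
})

test_that("with a pure-intercept outcome model the knee-level TKR rate matches logistic(intercept)", {
  cfg <- simConfig(nParticipants = 4800,
                   outcomeCoefficients = c(intercept = -2.5, severity = 0,
                                           age = 0, female = 0, bmi = 0,
                                           pain = 0),
                   outcomeWeightCoefs = c(overweight = 0, obese = 0),
                   outcomeKlCoef = 0)
  k <- generateCohort(cfg, seed = 3)$knees
  p <- plogis(-2.5)
  n <- nrow(k)
  expect_lt(abs(mean(k$tkr) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("marginal participant-level TKR incidence is calibrated to target", {
  cfg <- simConfig()  # default 4800 participants, 7% target
  k <- generateCohort(cfg, seed = 4)$knees
  inc <- mean(tapply(k$tkr, k$participant_id, any))
  se <- sqrt(0.07 * 0.93 / cfg$nParticipants)
  expect_lt(abs(inc - 0.07), 3 * se)
  expect_error(generateCohort(simConfig(tkrTargetRate = 0), seed = 1),
               "probabilities|strictly between")
})

test_that("severity is higher among TKR knees (confounded outcome)", {
  k <- generateCohort(simConfig(), seed = 5)$knees
  tt <- t.test(k$severity[k$tkr], k$severity[!k$tkr], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("KL grade increases monotonically with mean severity by construction", {
  k <- generateCohort(simConfig(), seed = 6)$knees
  m <- tapply(k$severity, k$kl_grade, mean)
  expect_false(is.unsorted(m))
  expect_true(all(k$kl_grade %in% c(0:4, NA)))
  expect_true(all(k$nrs_pain %in% c(0:10, NA)))
  expect_true(all(k$age >= 45))
  expect_true(all(is.na(k$tkr_interval_years) != k$tkr))
})

test_that("shape generation is deterministic and the noiseless template is exact", {
  cfg <- simConfig(nPointsPerBone = 80)
  a <- generateShape(1.3, "femur", cfg, seed = 7)
  b <- generateShape(1.3, "femur", cfg, seed = 7)
  expect_identical(a, b)
  cfg0 <- simConfig(nPointsPerBone = 80, shapeNoiseSd = 1e-12,
                    modeSds = rep(0, 5))
  tmpl <- tkrshape:::boneTemplate("femur", 80, 5)$points
  P <- generateShape(0, "femur", cfg0, seed = 8, pose = FALSE)
  expect_lt(max(abs(P - tmpl)), 1e-9)
  expect_error(generateShape(Inf, "femur", cfg), "finite")
  expect_error(generateShape(0, "fibula", cfg), "unknown bone")
})

test_that("training set reproduces the 53/43 OA split of 96 labelled shapes", {
  cfg <- simConfig(nPointsPerBone = 60)
  train <- generateTrainingSet(cfg, seed = 9, bone = "tibia")
  kl <- klGrades(train)
  expect_equal(nSamples(train), 96L)
  expect_equal(sum(kl >= 2), 53L)
  expect_equal(sum(kl <= 1), 43L)
  expect_true(all(kl %in% 0:4))
})

test_that("mean scores increase strictly with injected severity end to end", {
  cfg <- simConfig(nPointsPerBone = 120, nTrain = 32)
  m <- fitShapeModel(generateTrainingSet(cfg, seed = 10, bone = "femur"))
  sev <- rep(c(-1, 0, 1, 2), each = 8)
  shp <- generateShapes(sev, "femur", cfg, seed = 11)
  b <- scoreShapes(shp, m)$b
  means <- tapply(b, sev, mean)
  expect_true(all(diff(means) > 0))
})

test_that("test-retest pairs share true shape; zero noise gives SDD 0", {
  cfg0 <- simConfig(nPointsPerBone = 80, nTrain = 24, shapeNoiseSd = 1e-13)
  m <- fitShapeModel(generateTrainingSet(cfg0, seed = 12, bone = "femur"))
  tr <- generateTestRetest(10, cfg0, seed = 13, bone = "femur")
  b1 <- scoreShapes(tr$test, m)$b
  b2 <- scoreShapes(tr$retest, m)$b
  expect_lt(smallestDetectableDifference(b1, b2), 1e-6)
  # default noise: positive SDD
  cfg <- simConfig(nPointsPerBone = 80, nTrain = 24)
  tr2 <- generateTestRetest(35, cfg, seed = 14, bone = "femur")
  sdd <- smallestDetectableDifference(scoreShapes(tr2$test, m)$b,
                                      scoreShapes(tr2$retest, m)$b)
  expect_gt(sdd, 0)
  expect_error(generateTestRetest(1, cfg, seed = 1), ">= 2")
})

test_that("doubling the shape noise approximately doubles the SDD", {
  cfg1 <- simConfig(nPointsPerBone = 100, nTrain = 24, shapeNoiseSd = 0.3)
  cfg2 <- simConfig(nPointsPerBone = 100, nTrain = 24, shapeNoiseSd = 0.6)
  m <- fitShapeModel(generateTrainingSet(cfg1, seed = 20, bone = "femur"))
  n <- 1000
  tr1 <- generateTestRetest(n, cfg1, seed = 21, bone = "femur")
  tr2 <- generateTestRetest(n, cfg2, seed = 21, bone = "femur")
  s1 <- smallestDetectableDifference(scoreShapes(tr1$test, m)$b,
                                     scoreShapes(tr1$retest, m)$b)
  s2 <- smallestDetectableDifference(scoreShapes(tr2$test, m)$b,
                                     scoreShapes(tr2$retest, m)$b)
  expect_gt(s2 / s1, 1.7)
  expect_lt(s2 / s1, 2.3)
})
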