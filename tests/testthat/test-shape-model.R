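smallConfig <- function() simConfig(nPointsPerBone = 120L, nTrain = 24L)

test_that("rank-1 training data yields a single dominant component", {
  set.seed(2)
  base <- matrix(rnorm(60, sd = 10), 20, 3)
  v <- matrix(rnorm(60), 20, 3); v <- v / sqrt(sum(v^2))
  tvals <- seq(-2, 2, length.out = 12)
  arr <- array(NA_real_, c(20, 3, 12))
  for (i in seq_along(tvals)) arr[, , i] <- base + tvals[i] * v
  s <- ShapeSet(arr, "femur", klGrade = rep(c(0, 3), each = 6))
  m <- fitShapeModel(s, varFrac = 0.98)
  expect_equal(ncol(m@basis), 1L)
  expect_gt(m@eigenvalues[1], 0)
})

test_that("identical OA and non-OA groups are rejected as degenerate", {
  set.seed(4)
  P <- matrix(rnorm(45, sd = 5), 15, 3)
  arr <- array(rep(P, 4), c(15, 3, 4))
  arr <- arr + array(rnorm(length(arr), sd = 1e-9), dim(arr))  # avoid exact rank 0
  s <- ShapeSet(arr, "femur", klGrade = c(0, 3, 0, 3))
  expect_error(fitShapeModel(s), "degenerate|coincide")
})

test_that("training shapes with missing KL are excluded; empty group rejected", {
  cfg <- smallConfig()
  train <- generateTrainingSet(cfg, seed = 9, bone = "tibia")
  kl <- klGrades(train)
  kl[1:3] <- NA
  train@klGrade <- kl
  expect_message(m <- fitShapeModel(train), "missing KL")
  expect_equal(m@nTrainOA + m@nTrainNonOA, nSamples(train) - 3L)
  onlyOA <- train[which(klGrades(train) >= 2)]
  expect_error(fitShapeModel(onlyOA), "non-OA")
  expect_error(fitShapeModel(train, varFrac = 0), "varFrac")
  expect_error(fitShapeModel(train, varFrac = 1.2), "varFrac")
})

test_that("training group mean shapes score exactly -1 and +1", {
  cfg <- smallConfig()
  for (b in c("femur", "patella")) {
    m <- fitShapeModel(generateTrainingSet(cfg, seed = 5, bone = b))
    expect_lt(abs(scoreShapes(shapeFromScores(m, m@mOA), m) - 1), 1e-8)
    expect_lt(abs(scoreShapes(shapeFromScores(m, m@mNonOA), m) + 1), 1e-8)
  }
})

test_that("scoring is linear along the OA vector and blind to orthogonal offsets", {
  cfg <- smallConfig()
  m <- fitShapeModel(generateTrainingSet(cfg, seed = 6, bone = "femur"))
  delta <- m@mOA - m@mNonOA
  # t = 2 on the segment parameterization maps to b = 2t - 1 = 3
  expect_equal(scoreShapes(shapeFromScores(m, m@mNonOA + 2 * delta), m), 3,
               tolerance = 1e-8)
  set.seed(8)
  u <- delta / sqrt(sum(delta^2))
  perp <- rnorm(length(u)); perp <- perp - sum(perp * u) * u
  mid <- (m@mOA + m@mNonOA) / 2
  expect_lt(abs(scoreShapes(shapeFromScores(m, mid + 2 * perp), m,
                            align = FALSE)), 1e-8)
})

test_that("scores are invariant to rigid motion of the input", {
  cfg <- smallConfig()
  m <- fitShapeModel(generateTrainingSet(cfg, seed = 7, bone = "femur"))
  set.seed(10)
  for (i in 1:5) {
    P <- generateShape(runif(1, -1, 2), "femur", cfg, seed = i)
    b0 <- scoreShapes(P, m)
    moved <- sweep(P %*% randomRotation(), 2, runif(3, -100, 100), `+`)
    expect_lt(abs(scoreShapes(moved, m) - b0), 1e-6)
  }
})

test_that("bone and point-count mismatches are rejected", {
  cfg <- smallConfig()
  m <- fitShapeModel(generateTrainingSet(cfg, seed = 5, bone = "femur"))
  tib <- generateShapes(0.5, "tibia", cfg, seed = 1)
  expect_error(scoreShapes(tib, m), "bone mismatch")
  expect_error(scoreShapes(matrix(0, 7, 3), m), "nPoints x 3")
})

test_that("shape model JSON round trip leaves scores stable to 1e-10", {
  cfg <- smallConfig()
  m <- fitShapeModel(generateTrainingSet(cfg, seed = 12, bone = "patella"))
  path <- tempfile(fileext = ".json")
  writeShapeModel(m, path)
  m2 <- readShapeModel(path)
  expect_equal(m2@bone, m@bone)
  set.seed(13)
  shp <- generateShapes(c(-0.5, 0.3, 1.4), "patella", cfg, seed = 2)
  expect_lt(max(abs(scoreShapes(shp, m2)$b - scoreShapes(shp, m)$b)), 1e-10)
  unlink(path)
})
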