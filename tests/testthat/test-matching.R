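test_that("age bands and merged WHO weight categories follow the cut rules", {
  rec <- data.frame(age = c(45, 49.9, 64.9, 75, 83),
                    bmi = c(17, 18.0, 24.9, 29.9, 30.0))
  out <- categorizeCovariates(rec)
  expect_equal(as.character(out$age_band),
               c("45-49", "45-49", "60-64", "75+", "75+"))
  expect_equal(as.character(out$weight_category),
               c("normal/underweight", "normal/underweight",
                 "normal/underweight", "overweight", "obese"))
  expect_error(categorizeCovariates(data.frame(age = 30, bmi = 25)), "age")
  expect_error(categorizeCovariates(data.frame(age = 50, bmi = -1)), "bmi")
})

psToyData <- function(n, betaPain = 0.4) {
  # single continuous covariate embedded in the full design
  data.frame(knee_id = sprintf("k%03d", seq_len(n)),
             age = runif(n, 45, 79), gender = sample(c("male", "female"), n, TRUE),
             bmi = runif(n, 20, 35), side = sample(c("left", "right"), n, TRUE),
             nrs_pain = sample(0:10, n, TRUE))
}

test_that("logistic PS slope matches the 2x2 closed form", {
  # single binary covariate with all four cells filled:
  # beta = log(ad / bc)
  cells <- c(a = 30, b = 50, c = 20, d = 70)  # exposed-case, exposed-ctrl, unexp-case, unexp-ctrl
  x <- c(rep(1, cells["a"] + cells["b"]), rep(0, cells["c"] + cells["d"]))
  y <- c(rep(1, cells["a"]), rep(0, cells["b"]),
         rep(1, cells["c"]), rep(0, cells["d"]))
  fit <- glm(y ~ x, family = binomial())
  closed <- log((cells["a"] * cells["d"]) / (cells["b"] * cells["c"]))
  expect_equal(unname(coef(fit)["x"]), unname(closed), tolerance = 1e-6)
})

test_that("fitPs returns finite coefficients and per-knee scores; null design has no spurious signal", {
  set.seed(30)
  zExceed <- vapply(1:100, function(i) {
    d <- psToyData(300)
    d$case <- rbinom(300, 1, 0.4)  # outcome independent of covariates
    f <- fitPs(d)
    z <- f$model@coefficients[-1] / f$model@se[-1]
    any(abs(z) > 4)
  }, logical(1))
  expect_gte(mean(!zExceed), 0.99)
})

test_that("separation and aliased designs are reported", {
  set.seed(31)
  d <- psToyData(80)
  d$case <- as.integer(d$nrs_pain >= 5)  # perfectly separated by pain
  expect_warning(withCallingHandlers(
    fitPs(d),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }), "separation")
  d2 <- psToyData(60)
  d2$case <- rbinom(60, 1, 0.5)
  d2$nrs_pain <- NA_integer_
  expect_error(fitPs(d2), "non-missing")
})

test_that("nearest-neighbour matching is deterministic with documented tie rules", {
  cases <- data.frame(knee_id = c("c1", "c2"), gender = c("female", "male"))
  controls <- data.frame(knee_id = c("k1", "k2", "k3"),
                         gender = c("female", "male", "female"))
  ps <- c(c1 = 0.8, c2 = 0.5, k1 = 0.7, k2 = 0.9, k3 = 0.5)
  p <- matchPairs(cases, controls, ps)
  # case c1 (highest ps first): k1 and k2 tie at |d| = 0.1 -> knee_id order -> k1
  expect_equal(p$control_id[p$case_id == "c1"], "k1")
  expect_equal(p$control_id[p$case_id == "c2"], "k3")
  expect_identical(p, matchPairs(cases, controls, ps))
  # single case, single control
  p1 <- matchPairs(cases[1, ], controls[1, ], ps)
  expect_equal(nrow(p1), 1L)
  expect_error(matchPairs(cases, controls[1, , drop = FALSE], ps),
               "exhausted")
})

test_that("controls are never reused and exact matches are counted at 2 dp", {
  set.seed(32)
  cases <- data.frame(knee_id = sprintf("c%02d", 1:20))
  controls <- data.frame(knee_id = sprintf("k%02d", 1:60))
  ps <- c(runif(20, 0.2, 0.8), runif(60, 0.1, 0.9))
  names(ps) <- c(cases$knee_id, controls$knee_id)
  p <- matchPairs(cases, controls, ps)
  expect_false(any(duplicated(p$control_id)))
  expect_equal(attr(p, "n_exact"),
               sum(round(p$ps_case, 2) == round(p$ps_control, 2)))
  expect_equal(attr(p, "max_abs_diff"), max(p$abs_ps_diff))
})

test_that("greedy matching never beats the exhaustive optimal assignment", {
  set.seed(33)
  for (i in 1:100) {
    nC <- sample(2:6, 1); nK <- nC + sample(0:3, 1)
    psC <- round(runif(nC), 3); psK <- round(runif(nK), 3)
    cases <- data.frame(knee_id = sprintf("c%02d", seq_len(nC)))
    controls <- data.frame(knee_id = sprintf("k%02d", seq_len(nK)))
    ps <- c(psC, psK); names(ps) <- c(cases$knee_id, controls$knee_id)
    p <- matchPairs(cases, controls, ps)
    expect_gte(sum(p$abs_ps_diff) + 1e-12, optimalMatchCost(psC, psK))
  }
})

test_that("exact-gender matching yields full gender concordance", {
  set.seed(34)
  cases <- data.frame(knee_id = sprintf("c%02d", 1:15),
                      gender = sample(c("male", "female"), 15, TRUE))
  controls <- data.frame(knee_id = sprintf("k%02d", 1:50),
                         gender = sample(c("male", "female"), 50, TRUE))
  ps <- setNames(runif(65), c(cases$knee_id, controls$knee_id))
  p <- matchPairs(cases, controls, ps, exactGender = TRUE)
  g <- merge(merge(p, setNames(cases, c("case_id", "g_case")), by = "case_id"),
             setNames(controls, c("control_id", "g_ctrl")), by = "control_id")
  expect_true(all(g$g_case == g$g_ctrl))
})

test_that("standardized differences follow the stated formulas", {
  # continuous: means 5 vs 4, both sd 2 -> 50%
  x <- c(3, 5, 7); y <- c(2, 4, 6)  # sds equal 2, means 5 and 4
  cases <- data.frame(knee_id = c("a", "b", "c"), age = x, bmi = x,
                      nrs_pain = x, gender = "female", side = "right")
  ctrls <- data.frame(knee_id = c("d", "e", "f"), age = y, bmi = y,
                      nrs_pain = y, gender = "female", side = "right")
  rep <- balanceReport(cases, ctrls)
  expect_equal(rep$std_diff[rep$covariate == "age"], 50)
  # identical arms -> 0 everywhere it is defined
  rep0 <- balanceReport(cases, cases)
  expect_true(all(rep0$std_diff[rep0$type == "continuous"] == 0))
  # equal prevalences -> 0; all-same-level -> undefined (NA)
  cases$gender <- c("female", "male", "female")
  ctrls$gender <- c("male", "female", "female")
  rep2 <- balanceReport(cases, ctrls)
  expect_equal(rep2$std_diff[rep2$covariate == "gender_female"], 0)
  expect_true(is.na(rep2$std_diff[rep2$covariate == "side_right"]))
})
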