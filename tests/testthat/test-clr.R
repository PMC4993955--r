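test_that("binary-covariate CLR equals the discordant-pair ratio", {
  # 20 pairs case-exposed only, 10 control-exposed only -> OR = 2, beta = ln 2
  fit <- fitClr(c(rep(1, 20), rep(0, 10), rep(1, 5)),
                c(rep(0, 20), rep(1, 10), rep(1, 5)))
  expect_equal(unname(fit@beta), log(2), tolerance = 1e-8)
  expect_equal(fit@nInformative, 30L)
  expect_equal(fit@nPairs, 35L)
  # concordant pairs contribute log(1/2) each to the log likelihood
  ll30 <- fitClr(c(rep(1, 20), rep(0, 10)), c(rep(0, 20), rep(1, 10)))@logLik
  expect_equal(fit@logLik, ll30 + 5 * log(0.5), tolerance = 1e-8)
})

test_that("case/control-symmetric covariates give beta 0 and degenerate inputs fail", {
  x <- c(1, 2, 3, 1, 2, 3)
  y <- c(2, 3, 1, 2, 3, 1)
  fit <- fitClr(c(x, y), c(y, x))  # swap-symmetric
  expect_lt(abs(fit@beta), 1e-8)
  expect_error(fitClr(c(1, 1), c(1, 1)), "no informative pairs")
  expect_error(fitClr(c(NA, 1), c(0, 0)), "finite")
})

test_that("monotone likelihood (all discordant pairs concordant in sign) is reported", {
  expect_error(fitClr(rep(1, 15), rep(0, 15)),
               "divergent|monotone|singular")
})

test_that("CLR equals no-intercept logistic regression on within-pair differences", {
  set.seed(40)
  compared <- 0L
  for (i in 1:110) {
    n <- sample(20:60, 1)
    k <- sample(1:3, 1)
    sim <- simulateClrPairs(n, beta = runif(k, -1, 1))
    fit <- tryCatch(fitClr(sim$xCase, sim$xControl),
                    error = function(e) conditionMessage(e))
    d <- sim$xCase - sim$xControl
    ref <- suppressWarnings(
      glm(rep(1, n) ~ 0 + d, family = binomial(),
          control = glm.control(epsilon = 1e-12, maxit = 100)))
    if (is.character(fit)) {
      # a reported divergence must correspond to a (quasi-)separated
      # likelihood: the unconstrained oracle runs to an extreme estimate too
      expect_gt(max(abs(coef(ref))), 10)
    } else {
      expect_equal(unname(fit@beta), unname(coef(ref)), tolerance = 1e-6)
      compared <- compared + 1L
    }
  }
  expect_gte(compared, 100L)
})

test_that("CLR agrees with survival::clogit on coefficients, SEs and logLik", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  set.seed(41)
  sim <- simulateClrPairs(120, beta = c(0.7, -0.3))
  fit <- fitClr(sim$xCase, sim$xControl, terms = c("v1", "v2"))
  df <- data.frame(y = rep(c(1, 0), each = 120),
                   v1 = c(sim$xCase[, 1], sim$xControl[, 1]),
                   v2 = c(sim$xCase[, 2], sim$xControl[, 2]),
                   strat = rep(seq_len(120), 2))
  cl <- survival::clogit(y ~ v1 + v2 + strata(strat), data = df)
  expect_equal(unname(fit@beta), unname(coef(cl)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit@cov))), unname(sqrt(diag(vcov(cl)))),
               tolerance = 1e-5)
  expect_equal(fit@logLik, as.numeric(logLik(cl)), tolerance = 1e-6)
})

test_that("AIC table follows 2k - 2 logLik, refuses mixed samples, respects nesting", {
  set.seed(42)
  sim <- simulateClrPairs(150, beta = c(0.6, 0.2))
  f1 <- fitClr(sim$xCase[, 1], sim$xControl[, 1], terms = "v1")
  f2 <- fitClr(sim$xCase, sim$xControl, terms = c("v1", "v2"))
  expect_equal(f1@aic, 2 * 1 - 2 * f1@logLik)
  tab <- compareAic(list(small = f1, large = f2))
  expect_equal(tab$AIC, sort(tab$AIC))
  expect_equal(tab$deltaAIC[1], 0)
  # nested: larger model's logLik is no smaller
  expect_gte(f2@logLik, f1@logLik - 1e-10)
  f3 <- fitClr(sim$xCase[1:100, 1], sim$xControl[1:100, 1])
  expect_error(compareAic(list(f1, f3)), "different pair samples")
})

test_that("AIC ordering is invariant to adding a constant to a covariate", {
  set.seed(43)
  sim <- simulateClrPairs(200, beta = 0.5)
  f <- fitClr(sim$xCase, sim$xControl)
  fShift <- fitClr(sim$xCase + 7.3, sim$xControl + 7.3)
  expect_equal(f@aic, fShift@aic, tolerance = 1e-8)
  expect_equal(unname(f@beta), unname(fShift@beta), tolerance = 1e-8)
})

test_that("Wald odds-ratio intervals follow exp(beta +/- 1.96 se)", {
  fit <- fitClr(c(rep(1, 24), rep(0, 12)), c(rep(0, 24), rep(1, 12)))
  or <- oddsRatios(fit)
  se <- unname(sqrt(diag(fit@cov)))
  expect_equal(or$or, exp(unname(fit@beta)))
  expect_equal(or$or_low, exp(unname(fit@beta) - qnorm(0.975) * se),
               tolerance = 1e-10)
  expect_equal(or$or_high, exp(unname(fit@beta) + qnorm(0.975) * se),
               tolerance = 1e-10)
})

test_that("paired t matches the textbook formulas and flags degenerate data", {
  r <- pairedT(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
  expect_equal(r$mean_diff, 2)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  tt <- t.test(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  expect_equal(r$ci, unname(tt$conf.int[1:2]), tolerance = 1e-12)
  d <- pairedT(c(1, 2, 3), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$mean_diff, 0)
  expect_error(pairedT(1, 1), "at least 2")
})

test_that("tertile assignment partitions evenly with distinct values", {
  t9 <- assignTertiles(as.numeric(1:9))
  expect_equal(as.integer(table(t9$labels)), rep(3L, 3))
  expect_error(assignTertiles(rep(1, 10)), "distinct")
  set.seed(44)
  for (i in 1:20) {
    n <- 3 * sample(3:30, 1)
    x <- sample(seq_len(1000), n)  # distinct
    tt <- assignTertiles(x)
    expect_lte(diff(range(table(tt$labels))), 1)
  }
  # ties at a cut point fall in the lower tertile
  x <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  ta <- assignTertiles(x)
  expect_true(all(ta$labels[x == 2] != "highest"))
})

test_that("stratified fits: single stratum equals unstratified; empty strata logged", {
  set.seed(45)
  sim <- simulateClrPairs(80, beta = 0.6)
  whole <- fitClr(sim$xCase, sim$xControl)
  one <- stratifiedClr(sim$xCase, sim$xControl, strata = rep("all", 80))
  expect_equal(unname(one$fits$all@beta), unname(whole@beta), tolerance = 1e-10)
  lv <- factor(rep("a", 80), levels = c("a", "b"))
  two <- stratifiedClr(sim$xCase, sim$xControl, strata = lv)
  expect_true("b" %in% two$log$stratum)
  noInf <- stratifiedClr(matrix(1, 10, 1), matrix(1, 10, 1),
                         strata = rep("x", 10))
  expect_match(noInf$log$reason, "informative")
  small <- stratifiedClr(sim$xCase[1:5, , drop = FALSE],
                         sim$xControl[1:5, , drop = FALSE],
                         strata = rep("tiny", 5))
  expect_true("tiny" %in% small$flagged)
})

test_that("stratum estimates from a common truth fall within each other's CIs", {
  set.seed(46)
  hits <- vapply(1:40, function(i) {
    s1 <- simulateClrPairs(150, beta = 0.5)
    s2 <- simulateClrPairs(150, beta = 0.5)
    f <- stratifiedClr(rbind(s1$xCase, s2$xCase), rbind(s1$xControl, s2$xControl),
                       strata = rep(c("a", "b"), each = 150))$fits
    b <- vapply(f, function(x) unname(x@beta), numeric(1))
    se <- vapply(f, function(x) sqrt(x@cov[1, 1]), numeric(1))
    (abs(b["a"] - b["b"]) < 1.96 * se["a"]) ||
      (abs(b["a"] - b["b"]) < 1.96 * se["b"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
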