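#' Generate a synthetic OAI-like knee cohort
#'
#' Draws, from the distributions in a [simConfig()], a participant table and
#' two knees per participant: baseline covariates (age, gender, BMI, pain
#' NRS, health insurance), a latent per-knee OA severity that induces
#' confounding (it depends on age and BMI and drives KL grade, pain and the
#' TKR outcome), KL grades with missingness, and TKR outcomes from a logistic
#' model whose intercept is calibrated so the marginal participant-level
#' incidence matches `config$tkrTargetRate`.
#'
#' The latent `severity` column is simulation truth: downstream analysis
#' stages never read it, but tests and the score-validation workflow do.
#'
#' @param config A [simConfig()].
#' @param seed Integer seed; identical `(config, seed)` gives identical
#'   output.
#' @return A list with:
#'   \describe{
#'     \item{knees}{`data.frame`, one row per knee: `participant_id`,
#'       `knee_id`, `side`, `age`, `gender`, `bmi`, `nrs_pain`, `kl_grade`,
#'       `severity`, `shape_severity` (both simulation truth), `tkr`,
#'       `tkr_interval_years`, `indication`, `insurance`, `has_shape`.}
#'     \item{truth}{list with the realized outcome coefficients (including
#'       the calibrated intercept) and the severity table.}
#'   }
#' @examples
#' cohort <- generateCohort(simConfig(nParticipants = 100), seed = 1)
#' head(cohort$knees)
#' @export
generateCohort <- function(config = simConfig(), seed = 1L) {
  validateSimConfig(config)
  if (config$tkrTargetRate <= 0 || config$tkrTargetRate >= 1)
    stop("tkrTargetRate must lie strictly between 0 and 1 (calibration is impossible at 0 or 1)")
  np <- config$nParticipants
  withSeed(childSeed(seed, "cohort"), {
    # participant-level covariates
    lo <- stats::pnorm(config$ageRange[1], config$ageMean, config$ageSd)
    hi <- stats::pnorm(config$ageRange[2], config$ageMean, config$ageSd)
    age <- stats::qnorm(stats::runif(np, lo, hi), config$ageMean, config$ageSd)
    female <- stats::rbinom(np, 1L, config$femaleProb) == 1L
    bmi <- stats::rlnorm(np, config$bmiMeanLog, config$bmiSdLog)
    zShared <- stats::rnorm(np)

    # knee-level structure (left then right, interleaved by participant)
    pid <- rep(seq_len(np), each = 2L)
    side <- rep(c("left", "right"), np)
    zOwn <- stats::rnorm(2L * np)
    rho <- config$severityCor
    noise <- config$severityNoiseSd *
      (sqrt(rho) * zShared[pid] + sqrt(1 - rho) * zOwn)
    # weight acts on severity as a WHO-category step function of BMI
    wcat <- findInterval(bmi[pid], c(25, 30))  # 0 normal, 1 overweight, 2 obese
    sevW <- c(0, config$sevWeightCoefs[["overweight"]],
              config$sevWeightCoefs[["obese"]])[wcat + 1L]
    severity <- config$sevAgeCoef * (age[pid] - 61) +
      config$sevBmiCoef * (bmi[pid] - 28.5) + sevW + noise

    # the bone's true OA-mode deformation amplitude: a strong but imperfect
    # correlate of the latent severity that drives KL, pain and the outcome
    shapeSeverity <- severity + stats::rnorm(2L * np, 0, config$shapeBioNoiseSd)

    klTrue <- as.integer(cut(severity, c(-Inf, config$klCutPoints, Inf),
                             labels = FALSE)) - 1L
    kl <- klTrue
    kl[stats::runif(2L * np) < config$klMissingRate] <- NA_integer_

    pain <- round(config$painBase + config$painAlpha * severity +
                    stats::rnorm(2L * np, 0, config$painNoiseSd))
    pain <- pmin(10L, pmax(0L, as.integer(pain)))
    painObs <- pain
    painObs[stats::runif(2L * np) < config$painMissingRate] <- NA_integer_
    bmiKnee <- bmi[pid]
    bmiObs <- bmiKnee
    bmiObs[stats::runif(2L * np) < config$bmiMissingRate] <- NA_real_

    # TKR outcome model: knee-level logistic in severity + confounders
    beta <- config$outcomeCoefficients
    outW <- c(0, config$outcomeWeightCoefs[["overweight"]],
              config$outcomeWeightCoefs[["obese"]])[wcat + 1L]
    lp0 <- beta[["severity"]] * severity +
      config$outcomeKlCoef * (klTrue - 2L) +
      beta[["age"]] * (age[pid] - 61) +
      beta[["female"]] * as.numeric(female[pid]) +
      beta[["bmi"]] * (bmiKnee - 28.5) +
      beta[["pain"]] * (pain - 3) + outW
    if (is.na(beta[["intercept"]])) {
      # participant-level marginal incidence: P(any knee) = 1 - prod(1 - p)
      target <- config$tkrTargetRate
      f <- function(a) {
        p <- stats::plogis(a + lp0)
        pAny <- 1 - (1 - p[seq(1, 2 * np, 2)]) * (1 - p[seq(2, 2 * np, 2)])
        mean(pAny) - target
      }
      intercept <- stats::uniroot(f, c(-30, 10), tol = 1e-10)$root
    } else {
      intercept <- beta[["intercept"]]
    }
    pTkr <- stats::plogis(intercept + lp0)
    tkr <- stats::rbinom(2L * np, 1L, pTkr) == 1L
    interval <- rep(NA_real_, 2L * np)
    interval[tkr] <- stats::runif(sum(tkr), 0, config$tkrIntervalMax)
    # guard the open-left bound Uniform(0, max]
    interval[tkr][interval[tkr] == 0] <- config$tkrIntervalMax

    indication <- rep(NA_character_, 2L * np)
    rec <- tkr & stats::runif(2L * np) < config$indicationRecordedRate
    isRa <- stats::runif(2L * np) < config$raIndicationRate
    indication[rec] <- ifelse(isRa[rec], "RA", "OA")

    insurance <- stats::rbinom(2L * np, 1L,
                               ifelse(tkr, config$insuranceProbTkr,
                                      config$insuranceProbNoTkr)) == 1L
    hasShape <- stats::rbinom(2L * np, 1L, config$shapeAvailableRate) == 1L

    knees <- data.frame(
      participant_id = sprintf("P%05d", pid),
      knee_id = sprintf("P%05d_%s", pid, ifelse(side == "left", "L", "R")),
      side = side,
      age = age[pid],
      gender = ifelse(female[pid], "female", "male"),
      bmi = bmiObs,
      nrs_pain = painObs,
      kl_grade = kl,
      severity = severity,
      shape_severity = shapeSeverity,
      tkr = tkr,
      tkr_interval_years = interval,
      indication = indication,
      insurance = insurance,
      has_shape = hasShape,
      stringsAsFactors = FALSE)

    coefOut <- beta
    coefOut[["intercept"]] <- intercept
    list(knees = knees,
         truth = list(coefficients = coefOut,
                      weight_coefficients = config$outcomeWeightCoefs,
                      severity = knees[, c("knee_id", "severity",
                                           "shape_severity")]))
  })
}

#' Write a cohort to disk (CSV + JSON truth sidecar)
#'
#' @param cohort Result of [generateCohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$knees, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(coefficients = as.list(cohort$truth$coefficients),
         severity = cohort$truth$severity),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
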