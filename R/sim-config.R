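#' Configuration for the synthetic OAI-like cohort generator
#'
#' Defines every distributional choice of the simulation in one validated
#' object. Defaults emulate the structure of the motivating multicentre knee
#' OA cohort: ~4,800 participants aged 45-79, 58% female, ~36% obese, a
#' latent per-knee OA severity driven by age and BMI that in turn drives
#' KL grade, pain and bone-shape deformation, and a total knee replacement
#' (TKR) outcome confounded by age, gender, BMI and pain with ~7% marginal
#' participant-level incidence.
#'
#' @param nParticipants Number of participants; each contributes two knees.
#' @param tkrTargetRate Target marginal participant-level TKR incidence; the
#'   outcome-model intercept is calibrated to hit it (unless an explicit
#'   intercept is supplied in `outcomeCoefficients`).
#' @param outcomeCoefficients Named log-odds coefficients of the knee-level
#'   TKR model: `intercept` (NA = calibrate), `severity`, `age` (per year,
#'   centred at 61), `female`, `bmi` (per kg/m^2, centred at 28.5; default 0
#'   because the weight effect acts through the WHO category), `pain`
#'   (per NRS point, centred at 3).
#' @param outcomeWeightCoefs Log-odds effects of the overweight and obese
#'   WHO categories (vs normal/underweight) on TKR, mirroring the strong
#'   categorical weight-TKR association of the emulated study.
#' @param outcomeKlCoef Direct log-odds effect of KL grade (per grade,
#'   centred at 2) on TKR, over and above latent severity: the radiographic
#'   grade is what the surgeon actually sees, so it directly influences the
#'   decision to operate.
#' @param severityNoiseSd SD of the latent severity around its age/weight
#'   trend.
#' @param severityCor Correlation of the two knees' severities within a
#'   participant (contralateral knees share anatomy and exposures).
#' @param sevAgeCoef,sevBmiCoef Linear effect of age and BMI on severity
#'   (`sevBmiCoef` defaults to 0; weight acts through categories).
#' @param sevWeightCoefs Severity increments for the overweight and obese
#'   categories; this is the `f(age, bmi)` trend of the latent severity, a
#'   step function of BMI.
#' @param shapeNoiseSd Per-coordinate iid Gaussian noise on shape points (mm),
#'   emulating segmentation/measurement error.
#' @param shapeBioNoiseSd SD of the per-knee biological shape amplitude
#'   around the latent severity: the bone's OA-mode deformation is
#'   `severity + N(0, shapeBioNoiseSd^2)`, so the shape vector is a strong
#'   but imperfect correlate of the severity that drives KL grade, pain and
#'   the surgical decision (as in real joints, where radiographic grade and
#'   bone shape are correlated yet distinct expressions of disease).
#' @param nPointsPerBone Points per synthetic bone surface.
#' @param nTrain Training-set size for the shape model (53/96 OA when 96).
#' @param nRandomModes Number of smooth nuisance shape modes.
#' @param modeSds SDs (mm) of the nuisance mode coefficients; default a
#'   decaying spectrum `0.8 * 0.7^(k-1)`.
#' @param klCutPoints Four increasing severity thresholds binning severity
#'   into KL grades 0-4.
#' @param klMissingRate,painMissingRate,bmiMissingRate Missingness rates for
#'   the respective baseline fields.
#' @param shapeAvailableRate Probability a knee has usable baseline imaging.
#' @param ageMean,ageSd,ageRange Truncated-normal age distribution (years).
#' @param femaleProb Probability a participant is female.
#' @param bmiMeanLog,bmiSdLog Log-normal BMI parameters (defaults give ~36%
#'   obese).
#' @param painBase,painAlpha,painNoiseSd Pain NRS model:
#'   `round(painBase + painAlpha * severity + N(0, painNoiseSd^2))` clamped
#'   to 0-10.
#' @param insuranceProbTkr,insuranceProbNoTkr Health-insurance probabilities.
#' @param indicationRecordedRate Fraction of TKR knees with a recorded
#'   surgical indication.
#' @param raIndicationRate Probability a recorded indication is rheumatoid
#'   arthritis rather than OA.
#' @param tkrIntervalMax TKR intervals are Uniform(0, `tkrIntervalMax`] years.
#' @return A validated list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(nParticipants = 200)
#' cfg$tkrTargetRate
#' @export
simConfig <- function(nParticipants = 4800L,
                      tkrTargetRate = 0.07,
                      outcomeCoefficients = c(intercept = NA, severity = 0.55,
                                              age = 0.025, female = 0.25,
                                              bmi = 0, pain = 0.08),
                      outcomeWeightCoefs = c(overweight = 0.3, obese = 0.6),
                      outcomeKlCoef = 0.25,
                      severityNoiseSd = 1.0,
                      severityCor = 0.6,
                      sevAgeCoef = 0.04,
                      sevBmiCoef = 0,
                      sevWeightCoefs = c(overweight = 0.12, obese = 0.25),
                      shapeNoiseSd = 0.3,
                      shapeBioNoiseSd = 0.25,
                      nPointsPerBone = 500L,
                      nTrain = 96L,
                      nRandomModes = 5L,
                      modeSds = NULL,
                      klCutPoints = c(-0.45, 0.05, 0.75, 1.65),
                      klMissingRate = 0.05,
                      painMissingRate = 0.02,
                      bmiMissingRate = 0.01,
                      shapeAvailableRate = 0.96,
                      ageMean = 61, ageSd = 9, ageRange = c(45, 80),
                      femaleProb = 0.58,
                      bmiMeanLog = log(28.2), bmiSdLog = 0.18,
                      painBase = 3, painAlpha = 1.1, painNoiseSd = 1.8,
                      insuranceProbTkr = 0.98, insuranceProbNoTkr = 0.96,
                      indicationRecordedRate = 0.7,
                      raIndicationRate = 0.003,
                      tkrIntervalMax = 7) {
  cfg <- list(nParticipants = as.integer(nParticipants),
              tkrTargetRate = tkrTargetRate,
              outcomeCoefficients = outcomeCoefficients,
              outcomeWeightCoefs = outcomeWeightCoefs,
              outcomeKlCoef = outcomeKlCoef,
              severityNoiseSd = severityNoiseSd, severityCor = severityCor,
              sevAgeCoef = sevAgeCoef, sevBmiCoef = sevBmiCoef,
              sevWeightCoefs = sevWeightCoefs,
              shapeNoiseSd = shapeNoiseSd,
              shapeBioNoiseSd = shapeBioNoiseSd,
              nPointsPerBone = as.integer(nPointsPerBone),
              nTrain = as.integer(nTrain),
              nRandomModes = as.integer(nRandomModes),
              modeSds = modeSds %||% (0.8 * 0.7^(seq_len(nRandomModes) - 1)),
              klCutPoints = klCutPoints,
              klMissingRate = klMissingRate,
              painMissingRate = painMissingRate,
              bmiMissingRate = bmiMissingRate,
              shapeAvailableRate = shapeAvailableRate,
              ageMean = ageMean, ageSd = ageSd, ageRange = ageRange,
              femaleProb = femaleProb,
              bmiMeanLog = bmiMeanLog, bmiSdLog = bmiSdLog,
              painBase = painBase, painAlpha = painAlpha,
              painNoiseSd = painNoiseSd,
              insuranceProbTkr = insuranceProbTkr,
              insuranceProbNoTkr = insuranceProbNoTkr,
              indicationRecordedRate = indicationRecordedRate,
              raIndicationRate = raIndicationRate,
              tkrIntervalMax = tkrIntervalMax)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  probs <- c(cfg$tkrTargetRate, cfg$klMissingRate, cfg$painMissingRate,
             cfg$bmiMissingRate, cfg$shapeAvailableRate, cfg$femaleProb,
             cfg$insuranceProbTkr, cfg$insuranceProbNoTkr,
             cfg$indicationRecordedRate, cfg$raIndicationRate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$nParticipants < 2L) stop("nParticipants must be >= 2")
  if (cfg$severityNoiseSd <= 0 || cfg$painNoiseSd <= 0)
    stop("standard deviations must be positive")
  if (cfg$shapeNoiseSd < 0)
    stop("shapeNoiseSd must be non-negative (0 = noiseless measurement)")
  if (cfg$shapeBioNoiseSd < 0) stop("shapeBioNoiseSd must be non-negative")
  if (cfg$severityCor < 0 || cfg$severityCor > 1)
    stop("severityCor must lie in [0, 1]")
  if (is.unsorted(cfg$klCutPoints, strictly = TRUE) ||
      length(cfg$klCutPoints) != 4L)
    stop("klCutPoints must be 4 strictly increasing thresholds")
  if (cfg$nPointsPerBone < 4L) stop("nPointsPerBone must be >= 4")
  if (cfg$nTrain < 4L) stop("nTrain must be >= 4")
  if (length(cfg$modeSds) != cfg$nRandomModes || any(cfg$modeSds < 0))
    stop("modeSds must be nRandomModes non-negative values")
  cn <- c("intercept", "severity", "age", "female", "bmi", "pain")
  if (!all(cn %in% names(cfg$outcomeCoefficients)))
    stop("outcomeCoefficients must name: ", paste(cn, collapse = ", "))
  wn <- c("overweight", "obese")
  if (!all(wn %in% names(cfg$outcomeWeightCoefs)) ||
      !all(wn %in% names(cfg$sevWeightCoefs)))
    stop("weight-category coefficient vectors must name: overweight, obese")
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d participants, target TKR incidence %.3f\n",
              x$nParticipants, x$tkrTargetRate))
  cat(sprintf("  severity noise sd %.2f (within-participant cor %.2f); shape noise sd %.2f mm\n",
              x$severityNoiseSd, x$severityCor, x$shapeNoiseSd))
  cat(sprintf("  %d points per bone, %d training shapes, %d nuisance modes\n",
              x$nPointsPerBone, x$nTrain, x$nRandomModes))
  invisible(x)
}
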