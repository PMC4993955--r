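#' Add age-band and weight-category columns
#'
#' Age is binned into 5-year bands (45-49, ..., 70-74, 75+). BMI is binned
#' into WHO categories with underweight merged into normal
#' (normal/underweight < 25, overweight 25-29.9, obese >= 30), mirroring the
#' merge used when very few participants are underweight.
#'
#' @param records Knee `data.frame` with `age` and `bmi`.
#' @return The `data.frame` with factor columns `age_band` and
#'   `weight_category` appended.
#' @export
categorizeCovariates <- function(records) {
  age <- records$age
  bmi <- records$bmi
  if (any(!is.na(age) & age < 45)) stop("age must be >= 45")
  if (any(!is.na(bmi) & bmi <= 0)) stop("bmi must be positive")
  bandLevels <- c("45-49", "50-54", "55-59", "60-64", "65-69", "70-74", "75+")
  idx <- pmin(floor((age - 45) / 5) + 1, 7)
  records$age_band <- factor(bandLevels[idx], levels = bandLevels)
  wcat <- ifelse(bmi < 25, "normal/underweight",
                 ifelse(bmi < 30, "overweight", "obese"))
  records$weight_category <- factor(
    wcat, levels = c("normal/underweight", "overweight", "obese"))
  records
}

#' Fit the propensity (stratification) score model
#'
#' Maximum-likelihood logistic regression of case status on the
#' pre-specified baseline covariates: age band, gender, weight category,
#' pain NRS (continuous) and knee side. KL grade is deliberately excluded
#' from the design: it directly drives the decision to operate (over-matching
#' risk) and is moderately correlated with the bone shape vector under study.
#'
#' @param records Stacked `data.frame` of cases and controls with a logical
#'   (or 0/1) `case` column and the covariates above (categorized via
#'   [categorizeCovariates()] if needed).
#' @return A list: `model` (a [PsModel-class]) and `ps` (fitted propensity
#'   scores named by `knee_id`).
#' @export
fitPs <- function(records) {
  if (!"age_band" %in% names(records) || !"weight_category" %in% names(records))
    records <- categorizeCovariates(records)
  need <- c("case", "age_band", "gender", "weight_category", "nrs_pain", "side")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(records[, need])
  if (!all(cc)) stop("model covariates and outcome must be non-missing")
  records$gender <- factor(records$gender, levels = c("male", "female"))
  records$side <- factor(records$side, levels = c("left", "right"))
  fit <- stats::glm(case ~ age_band + gender + weight_category + nrs_pain + side,
                    family = stats::binomial(), data = records,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  co <- stats::coef(fit)
  if (any(is.na(co))) {
    stop("singular design: aliased coefficient(s) ",
         paste(names(co)[is.na(co)], collapse = ", "))
  }
  p <- stats::fitted(fit)
  separation <- !fit$converged || any(abs(co) > 15) ||
    any(p > 1 - 1e-8 | p < 1e-8)
  if (separation)
    warning("possible complete or quasi-complete separation in the propensity model")
  ps <- as.numeric(p)
  names(ps) <- records$knee_id
  model <- new("PsModel", coefficients = co,
               se = sqrt(diag(stats::vcov(fit))),
               logLik = as.numeric(stats::logLik(fit)),
               n = nrow(records), converged = fit$converged,
               separation = separation)
  list(model = model, ps = ps)
}

setMethod("show", "PsModel", function(object) {
  cat(sprintf("PsModel: logistic propensity model, n = %d, logLik = %.2f%s\n",
              object@n, object@logLik,
              if (object@separation) " [separation suspected]" else ""))
  print(round(object@coefficients, 4))
  invisible(NULL)
})

#' Nearest-neighbour 1:1 propensity matching without replacement
#'
#' Greedy matching: cases are processed in descending propensity-score order
#' (ties broken by `knee_id`); each takes the unused control with the
#' smallest absolute score difference (ties again by `knee_id`). Controls are
#' never reused. No caliper is imposed; instead the maximum matched
#' difference and the number of exact matches (equal scores at two decimal
#' places) are reported, so closeness is an audited outcome rather than a
#' constraint.
#'
#' @param cases,controls `data.frame`s with a `knee_id` column.
#' @param ps Named propensity-score vector covering all case and control
#'   knee ids.
#' @param exactGender Require matched controls to share the case's gender
#'   (default `FALSE`; concordance is normally left to emerge from the score).
#' @return A `data.frame` of pairs (`case_id`, `control_id`, `ps_case`,
#'   `ps_control`, `abs_ps_diff`, `exact`) with attributes `n_exact` and
#'   `max_abs_diff`.
#' @export
matchPairs <- function(cases, controls, ps, exactGender = FALSE) {
  assertFlag(exactGender, "exactGender")
  if (nrow(controls) < nrow(cases))
    stop(sprintf("control pool exhausted before matching: %d cases but only %d controls",
                 nrow(cases), nrow(controls)))
  missing <- setdiff(c(cases$knee_id, controls$knee_id), names(ps))
  if (length(missing))
    stop("propensity scores missing for: ", paste(utils::head(missing, 5), collapse = ", "))
  psCase <- ps[cases$knee_id]
  psCtrl <- ps[controls$knee_id]
  ord <- order(-psCase, cases$knee_id)
  used <- rep(FALSE, nrow(controls))
  ctrlGender <- controls$gender
  out <- vector("list", nrow(cases))
  for (k in seq_along(ord)) {
    i <- ord[k]
    avail <- !used
    if (exactGender) avail <- avail & ctrlGender == cases$gender[i]
    if (!any(avail))
      stop(sprintf("control pool exhausted: no eligible control for case %s (%d cases unmatched)",
                   cases$knee_id[i], length(ord) - k + 1L))
    d <- abs(psCtrl - psCase[i])
    d[!avail] <- Inf
    best <- which(d <= min(d) + 1e-12)  # tolerance so float noise cannot mask ties
    if (length(best) > 1L) best <- best[order(controls$knee_id[best])][1]
    used[best] <- TRUE
    out[[k]] <- data.frame(case_id = cases$knee_id[i],
                           control_id = controls$knee_id[best],
                           ps_case = unname(psCase[i]),
                           ps_control = unname(psCtrl[best]),
                           abs_ps_diff = unname(d[best]),
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  pairs$exact <- round(pairs$ps_case, 2) == round(pairs$ps_control, 2)
  stopifnot(!anyDuplicated(pairs$control_id))
  attr(pairs, "n_exact") <- sum(pairs$exact)
  attr(pairs, "max_abs_diff") <- max(pairs$abs_ps_diff)
  pairs
}

stdDiffContinuous <- function(x, y) {
  s2 <- (stats::var(x) + stats::var(y)) / 2
  if (s2 <= 0) return(NA_real_)
  100 * (mean(x) - mean(y)) / sqrt(s2)
}

stdDiffBinary <- function(p1, p0) {
  s2 <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
  if (s2 <= 0) return(NA_real_)
  (p1 - p0) / sqrt(s2)
}

#' Covariate balance diagnostics on the matched sample
#'
#' Standardized differences between matched case and control arms: for
#' continuous covariates (age, BMI, pain analysed on their raw scales) the
#' mean difference as a percentage of the average standard deviation,
#' flagged against a 10% threshold; for dichotomous covariates (female
#' gender, right side) the prevalence difference divided by the pooled
#' within-group binomial SD, flagged against 0.1. A zero pooled SD yields
#' `NA` ("undefined") for that covariate.
#'
#' @param cases,controls Matched knee `data.frame`s, row i of each forming
#'   pair i.
#' @param ps Optional named propensity vector; when given, per-arm score
#'   summaries are attached as attribute `ps_summary`.
#' @return A `data.frame`: `covariate`, `type`, `std_diff`, `threshold`,
#'   `balanced`.
#' @export
balanceReport <- function(cases, controls, ps = NULL) {
  if (nrow(cases) != nrow(controls) || nrow(cases) < 2L)
    stop("need >= 2 matched pairs with equal arm sizes")
  rows <- list(
    data.frame(covariate = "age", type = "continuous",
               std_diff = stdDiffContinuous(cases$age, controls$age),
               threshold = 10),
    data.frame(covariate = "bmi", type = "continuous",
               std_diff = stdDiffContinuous(cases$bmi, controls$bmi),
               threshold = 10),
    data.frame(covariate = "nrs_pain", type = "continuous",
               std_diff = stdDiffContinuous(cases$nrs_pain, controls$nrs_pain),
               threshold = 10),
    data.frame(covariate = "gender_female", type = "dichotomous",
               std_diff = stdDiffBinary(mean(cases$gender == "female"),
                                        mean(controls$gender == "female")),
               threshold = 0.1),
    data.frame(covariate = "side_right", type = "dichotomous",
               std_diff = stdDiffBinary(mean(cases$side == "right"),
                                        mean(controls$side == "right")),
               threshold = 0.1))
  rep <- do.call(rbind, rows)
  rep$balanced <- ifelse(is.na(rep$std_diff), NA,
                         abs(rep$std_diff) < rep$threshold)
  if (!is.null(ps)) {
    summ <- function(v) c(mean = mean(v), sd = stats::sd(v),
                          median = stats::median(v))
    attr(rep, "ps_summary") <- rbind(case = summ(ps[cases$knee_id]),
                                     control = summ(ps[controls$knee_id]))
  }
  rep
}
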