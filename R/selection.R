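#' Apply case-definition and eligibility rules to a knee cohort
#'
#' Case knees: confirmed TKR with an OA indication (a recorded rheumatoid
#' arthritis indication excludes; when the indication is unrecorded, "OA
#' highly likely" is operationalized as baseline KL >= 2 and pain NRS >= 1).
#' Where a participant had both knees replaced, the first-replaced knee is
#' taken; same-day replacements are broken uniformly at random under the
#' supplied seed. Case and control status both require complete baseline
#' records (age, gender, pain, weight/BMI, KL grade) and usable baseline
#' shape data; ineligible knees are logged with one reason each.
#'
#' @param knees Cohort `data.frame` as produced by [generateCohort()].
#' @param seed Integer seed for same-day tie-breaking.
#' @return A list with `cases` (one knee per TKR participant) and
#'   `log` (`data.frame` of `knee_id`, `reason` covering every TKR knee not
#'   selected as a case).
#' @export
selectCases <- function(knees, seed = 1L) {
  tk <- knees[knees$tkr, , drop = FALSE]
  log <- data.frame(knee_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  addLog <- function(ids, reason) {
    if (length(ids))
      log <<- rbind(log, data.frame(knee_id = ids, reason = reason,
                                    stringsAsFactors = FALSE))
  }
  # indication filter (knee level, before first-replaced selection)
  ra <- !is.na(tk$indication) & tk$indication == "RA"
  addLog(tk$knee_id[ra], "non_oa_indication")
  tk <- tk[!ra, , drop = FALSE]
  unlikely <- is.na(tk$indication) &
    !(!is.na(tk$kl_grade) & tk$kl_grade >= 2L &
        !is.na(tk$nrs_pain) & tk$nrs_pain >= 1L)
  addLog(tk$knee_id[unlikely], "oa_indication_unlikely")
  tk <- tk[!unlikely, , drop = FALSE]

  # first-replaced knee per participant; same-day ties broken at random
  selected <- withSeed(childSeed(seed, "case_ties"), {
    keep <- logical(nrow(tk))
    for (p in unique(tk$participant_id)) {
      i <- which(tk$participant_id == p)
      if (length(i) == 1L) { keep[i] <- TRUE; next }
      iv <- tk$tkr_interval_years[i]
      best <- i[iv == min(iv)]
      pick <- if (length(best) == 1L) best else sample(best, 1L)
      keep[pick] <- TRUE
      keep[setdiff(i, pick)] <- FALSE
    }
    keep
  })
  addLog(tk$knee_id[!selected], "contralateral_replaced_later_or_same_day")
  tk <- tk[selected, , drop = FALSE]

  # completeness and imaging
  incomplete <- is.na(tk$age) | is.na(tk$gender) | is.na(tk$nrs_pain) |
    is.na(tk$bmi) | is.na(tk$kl_grade)
  addLog(tk$knee_id[incomplete], "missing_baseline")
  tk <- tk[!incomplete, , drop = FALSE]
  noShape <- !tk$has_shape
  addLog(tk$knee_id[noShape], "missing_shape")
  tk <- tk[!noShape, , drop = FALSE]

  list(cases = tk, log = log)
}

#' Choose one control knee among a participant's surviving knees
#'
#' The knee with the higher pain score; the right knee on an equal-pain tie;
#' the only knee when just one survives.
#'
#' @param participantKnees `data.frame` of 1-2 knee rows with `nrs_pain` and
#'   `side`.
#' @return One knee row.
#' @export
selectControlKnee <- function(participantKnees) {
  n <- nrow(participantKnees)
  if (n < 1L || n > 2L) stop("expected 1 or 2 surviving knees per participant")
  if (any(is.na(participantKnees$nrs_pain)))
    stop("pain scores must be present for control-knee selection")
  if (n == 1L) return(participantKnees)
  p <- participantKnees$nrs_pain
  if (p[1] != p[2]) return(participantKnees[which.max(p), , drop = FALSE])
  participantKnees[participantKnees$side == "right", , drop = FALSE]
}

#' Select cases and the eligible control pool from a cohort
#'
#' Combines [selectCases()] with the control-eligibility rules: a knee enters
#' the control pool if it was not replaced, has complete baseline records and
#' shape data, and is the participant's selected control knee (higher pain;
#' right on a tie). The surviving knee of a case participant can enter the
#' pool (contralateral controls are permitted).
#'
#' @param knees Cohort `data.frame`.
#' @param seed Integer seed (case same-day tie-breaks).
#' @return A list: `cases`, `controls`, `log` (excluded knees with reasons).
#' @examples
#' cohort <- generateCohort(simConfig(nParticipants = 300), seed = 2)
#' sel <- selectCohort(cohort$knees, seed = 2)
#' nrow(sel$cases); nrow(sel$controls)
#' @export
selectCohort <- function(knees, seed = 1L) {
  cs <- selectCases(knees, seed = seed)
  log <- cs$log

  surv <- knees[!knees$tkr, , drop = FALSE]
  incomplete <- is.na(surv$age) | is.na(surv$gender) | is.na(surv$nrs_pain) |
    is.na(surv$bmi) | is.na(surv$kl_grade)
  if (any(incomplete))
    log <- rbind(log, data.frame(knee_id = surv$knee_id[incomplete],
                                 reason = "missing_baseline"))
  surv <- surv[!incomplete, , drop = FALSE]
  noShape <- !surv$has_shape
  if (any(noShape))
    log <- rbind(log, data.frame(knee_id = surv$knee_id[noShape],
                                 reason = "missing_shape"))
  surv <- surv[!noShape, , drop = FALSE]

  pick <- unlist(lapply(split(seq_len(nrow(surv)), surv$participant_id),
                        function(i) {
    if (length(i) == 1L) return(i)
    sub <- surv[i, , drop = FALSE]
    i[match(selectControlKnee(sub)$knee_id, sub$knee_id)]
  }), use.names = FALSE)
  notPicked <- setdiff(seq_len(nrow(surv)), pick)
  if (length(notPicked))
    log <- rbind(log, data.frame(knee_id = surv$knee_id[notPicked],
                                 reason = "lower_pain_contralateral"))
  controls <- surv[sort(pick), , drop = FALSE]

  stopifnot(!anyDuplicated(c(cs$cases$knee_id, controls$knee_id)))
  list(cases = cs$cases, controls = controls, log = log)
}
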