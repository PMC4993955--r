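# Synthetic bone shapes: a deterministic superellipsoid-like template per
# bone, a fixed localized "marginal ridge" displacement field scaled by the
# latent OA severity (emulating osteophytic ridge growth and overall bone
# expansion at the cartilage-plate margins), smooth random nuisance modes,
# and iid Gaussian measurement noise.

boneTemplateParams <- function(bone) {
  switch(bone,
    femur   = list(ax = 45, ay = 40, az = 32, e1 = 0.9, e2 = 0.9),
    tibia   = list(ax = 38, ay = 36, az = 22, e1 = 0.8, e2 = 0.8),
    patella = list(ax = 22, ay = 20, az = 11, e1 = 1.0, e2 = 1.0),
    stop("unknown bone: ", bone))
}

spow <- function(x, e) sign(x) * abs(x)^e

# deterministic Fibonacci-spiral sampling of the parameter domain
templateAngles <- function(n) {
  i <- seq_len(n) - 1L
  z <- (2 * i + 1) / n - 1
  u <- asin(z)                           # latitude in [-pi/2, pi/2]
  phi <- (1 + sqrt(5)) / 2
  v <- (2 * pi * i / phi) %% (2 * pi) - pi  # longitude in [-pi, pi)
  list(u = u, v = v)
}

boneTemplateEnv <- new.env(parent = emptyenv())

#' Deterministic bone surface template
#'
#' @param bone Bone label.
#' @param n Number of surface points.
#' @return A list with `points` (`n x 3` mm), spherical parameters `u`, `v`,
#'   `radial` (unit outward directions), `vOA` (the OA displacement field,
#'   mm per severity unit) and `modes` (an `n x 3 x K` array of fixed smooth
#'   nuisance fields; coefficients are drawn per shape).
#' @keywords internal
boneTemplate <- function(bone, n, nModes = 5L) {
  key <- sprintf("%s_%d_%d", bone, n, nModes)
  if (!is.null(boneTemplateEnv[[key]])) return(boneTemplateEnv[[key]])
  p <- boneTemplateParams(bone)
  a <- templateAngles(n)
  cu <- cos(a$u); su <- sin(a$u); cv <- cos(a$v); sv <- sin(a$v)
  pts <- cbind(p$ax * spow(cu, p$e1) * spow(cv, p$e2),
               p$ay * spow(cu, p$e1) * spow(sv, p$e2),
               p$az * spow(su, p$e1))
  radial <- pts / sqrt(rowSums(pts^2))
  # marginal ridge: outward displacement in a band around the equator
  # (the cartilage-plate margin of the template), angularly modulated, plus
  # a small uniform expansion (bone area growth with disease)
  ridge <- 1.5 * exp(-(a$u / 0.25)^2) * (1 + 0.5 * cos(2 * a$v)) + 0.2
  vOA <- radial * ridge
  modes <- array(0, c(n, 3L, nModes))
  for (k in seq_len(nModes)) {
    f <- cos(k * a$v + 0.7 * k) * cos(((k %% 3) + 1) * a$u) +
         0.3 * sin((k + 1) * a$u)
    modes[, , k] <- radial * f
  }
  out <- list(points = pts, u = a$u, v = a$v, radial = radial,
              vOA = vOA, modes = modes)
  boneTemplateEnv[[key]] <- out
  out
}

randomRigidMotion <- function(P, maxAngle = 10 * pi / 180, maxShift = 20) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -maxAngle, maxAngle)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(P %*% R, 2L, stats::runif(3, -maxShift, maxShift), `+`)
}

#' Generate one synthetic bone shape
#'
#' `points = template + severity * V_OA + sum_k c_k V_k + noise`, followed by
#' a random rigid motion (scanner pose), where `V_OA` is the fixed marginal
#' ridge field and `V_k` are smooth nuisance modes with
#' `c_k ~ N(0, modeSds[k]^2)`.
#'
#' @param severity Latent OA severity (finite scalar; the training non-OA /
#'   OA group means sit near -0.9 / +1.1 on this scale under defaults).
#' @param bone Bone label.
#' @param config A [simConfig()].
#' @param seed Integer seed; identical `(severity, seed)` gives identical
#'   points.
#' @param pose Apply a random rigid motion (default `TRUE`).
#' @param modeCoefs Optional fixed nuisance-mode coefficients (used by
#'   [generateTestRetest()] so replicates share true shape).
#' @param noiseSd Per-coordinate noise SD; defaults to `config$shapeNoiseSd`.
#' @return `n x 3` coordinate matrix (mm).
#' @export
generateShape <- function(severity, bone, config = simConfig(), seed = 1L,
                          pose = TRUE, modeCoefs = NULL, noiseSd = NULL) {
  if (!is.finite(severity)) stop("severity must be finite")
  tmpl <- boneTemplate(bone, config$nPointsPerBone, config$nRandomModes)
  noiseSd <- noiseSd %||% config$shapeNoiseSd
  withSeed(seed, {
    cc <- modeCoefs %||% stats::rnorm(config$nRandomModes, 0, config$modeSds)
    P <- tmpl$points + severity * tmpl$vOA
    for (k in seq_len(config$nRandomModes)) P <- P + cc[k] * tmpl$modes[, , k]
    P <- P + matrix(stats::rnorm(length(P), 0, noiseSd), nrow(P), 3L)
    if (pose) P <- randomRigidMotion(P)
    P
  })
}

#' Generate a batch of shapes as a ShapeSet
#'
#' @param severities Numeric vector of latent severities.
#' @param bone Bone label.
#' @param config A [simConfig()].
#' @param seed Integer master seed (each shape gets a derived child seed).
#' @param kneeId,klGrade Optional identifiers and labels.
#' @param pose Apply random rigid motions.
#' @return A [ShapeSet-class] with severity recorded in `meta`.
#' @export
generateShapes <- function(severities, bone, config = simConfig(), seed = 1L,
                           kneeId = NULL, klGrade = NA, pose = TRUE) {
  n <- length(severities)
  kneeId <- kneeId %||% sprintf("sim_%s_%04d", bone, seq_len(n))
  arr <- array(NA_real_, c(config$nPointsPerBone, 3L, n))
  for (i in seq_len(n)) {
    arr[, , i] <- generateShape(severities[i], bone, config,
                                seed = childSeed(seed, paste0("shape_", kneeId[i])),
                                pose = pose)
  }
  ShapeSet(arr, bone, kneeId = kneeId, klGrade = klGrade,
           meta = data.frame(severity = severities))
}

#' Generate the KL-labelled shape-model training set
#'
#' Reproduces the study's training composition: for the default `nTrain = 96`,
#' 53 OA shapes (KL 2-4) and 43 non-OA shapes (KL 0-1), spread near-evenly
#' over the grades within each group. (The source description of the training
#' set as having "equal numbers per KL grade" is arithmetically inconsistent
#' with the reported 53/43 split of 96; the 53/43 split is reproduced here.)
#' Severities are drawn uniformly within each grade's severity bin.
#'
#' @param config A [simConfig()].
#' @param seed Integer seed.
#' @param bone Bone label.
#' @return A [ShapeSet-class] of `config$nTrain` labelled shapes.
#' @export
generateTrainingSet <- function(config = simConfig(), seed = 1L,
                                bone = "femur") {
  nOA <- round(config$nTrain * 53 / 96)
  nNon <- config$nTrain - nOA
  splitEven <- function(total, k) {
    base <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  kl <- c(rep(2:4, splitEven(nOA, 3L)), rep(0:1, splitEven(nNon, 2L)))
  cuts <- config$klCutPoints
  lo <- c(cuts[1] - 1.2, cuts)[kl + 1L]
  hi <- c(cuts, cuts[4] + 1.2)[kl + 1L]
  sev <- withSeed(childSeed(seed, "train_severity"),
                  stats::runif(length(kl), lo, hi))
  amp <- withSeed(childSeed(seed, "train_bio"),
                  sev + stats::rnorm(length(sev), 0, config$shapeBioNoiseSd))
  out <- generateShapes(amp, bone, config, seed = childSeed(seed, "train_shapes"),
                        kneeId = sprintf("train_%s_%03d", bone, seq_along(kl)),
                        klGrade = kl)
  out@meta <- data.frame(severity = sev, shape_severity = amp)
  out
}

#' Generate paired test-retest shape replicates
#'
#' Replicate pairs share the true shape (severity and nuisance-mode
#' coefficients) and differ only in measurement noise and pose, emulating
#' repeat MRI of the same knees about a week apart.
#'
#' @param nKnees Number of knees (`>= 2`).
#' @param config A [simConfig()].
#' @param seed Integer seed.
#' @param bone Bone label.
#' @param severityMean,severitySd Severity distribution of the replicate
#'   knees; defaults emulate an OA reproducibility set.
#' @return A list with [ShapeSet-class] elements `test` and `retest` (same
#'   kneeIds, same order) and the numeric `severity` vector.
#' @export
generateTestRetest <- function(nKnees, config = simConfig(), seed = 1L,
                               bone = "femur", severityMean = 1,
                               severitySd = 0.7) {
  if (nKnees < 2L) stop("nKnees must be >= 2")
  n <- config$nPointsPerBone
  sev <- withSeed(childSeed(seed, "retest_severity"),
                  stats::rnorm(nKnees, severityMean, severitySd))
  ids <- sprintf("retest_%s_%03d", bone, seq_len(nKnees))
  arrT <- array(NA_real_, c(n, 3L, nKnees))
  arrR <- array(NA_real_, c(n, 3L, nKnees))
  for (i in seq_len(nKnees)) {
    cc <- withSeed(childSeed(seed, paste0("retest_modes_", i)),
                   stats::rnorm(config$nRandomModes, 0, config$modeSds))
    arrT[, , i] <- generateShape(sev[i], bone, config,
                                 seed = childSeed(seed, paste0("retest_t_", i)),
                                 modeCoefs = cc)
    arrR[, , i] <- generateShape(sev[i], bone, config,
                                 seed = childSeed(seed, paste0("retest_r_", i)),
                                 modeCoefs = cc)
  }
  list(test = ShapeSet(arrT, bone, kneeId = ids,
                       meta = data.frame(severity = sev)),
       retest = ShapeSet(arrR, bone, kneeId = ids,
                         meta = data.frame(severity = sev)),
       severity = sev)
}
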