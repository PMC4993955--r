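#' @import methods
#' @importFrom stats coef vcov logLik
NULL

BONES <- c("femur", "tibia", "patella")

#' ShapeSet: corresponded 3D bone point clouds
#'
#' A set of bone surfaces for one bone type, each represented by the same
#' number of 3D points in point-to-point correspondence (point i on every
#' sample is the same anatomical location, as produced by an active
#' appearance model search or comparable correspondence method).
#'
#' @slot bone Character scalar, one of `"femur"`, `"tibia"`, `"patella"`.
#' @slot coords Numeric array `nPoints x 3 x nSamples` of coordinates in mm.
#' @slot kneeId Character vector of sample identifiers (unique).
#' @slot klGrade Integer vector of Kellgren-Lawrence grades 0-4, `NA` allowed.
#' @slot meta A `data.frame` with one row per sample for extra metadata
#'   (e.g. the latent severity of simulated shapes).
#' @export
setClass("ShapeSet",
  slots = c(bone = "character", coords = "array", kneeId = "character",
            klGrade = "integer", meta = "data.frame"))

setValidity("ShapeSet", function(object) {
  msg <- character()
  if (length(object@bone) != 1L || !object@bone %in% BONES)
    msg <- c(msg, sprintf("bone must be one of %s", paste(BONES, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nPoints x 3 x nSamples array")
  else {
    if (d[1] < 4L) msg <- c(msg, "at least 4 points per shape required")
    if (!all(is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
    if (length(object@kneeId) != d[3]) msg <- c(msg, "kneeId length != nSamples")
    if (anyDuplicated(object@kneeId)) msg <- c(msg, "kneeId values must be unique")
    if (length(object@klGrade) != d[3]) msg <- c(msg, "klGrade length != nSamples")
    if (nrow(object@meta) > 0L && nrow(object@meta) != d[3])
      msg <- c(msg, "meta must have one row per sample")
  }
  kl <- object@klGrade
  if (any(!is.na(kl) & (kl < 0L | kl > 4L)))
    msg <- c(msg, "klGrade must be in 0..4 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a ShapeSet
#'
#' @param coords `nPoints x 3 x nSamples` array, or a single `nPoints x 3`
#'   matrix for a one-sample set.
#' @param bone Bone label: `"femur"`, `"tibia"` or `"patella"`.
#' @param kneeId Character identifiers, one per sample.
#' @param klGrade Optional KL grades (0-4, `NA` allowed).
#' @param meta Optional per-sample `data.frame`.
#' @return A [ShapeSet-class] object.
#' @examples
#' pts <- replicate(3, matrix(rnorm(30), 10, 3))
#' ShapeSet(pts, "femur", kneeId = c("a", "b", "c"))
#' @export
ShapeSet <- function(coords, bone, kneeId = NULL, klGrade = NA, meta = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  n <- dim(coords)[3]
  if (is.null(kneeId)) kneeId <- sprintf("shape%03d", seq_len(n))
  klGrade <- as.integer(rep_len(klGrade, n))
  new("ShapeSet", bone = bone, coords = coords, kneeId = as.character(kneeId),
      klGrade = klGrade, meta = meta %||% data.frame())
}

#' ShapeModel: principal-component shape space with an OA discriminant vector
#'
#' Fitted by [fitShapeModel()]: the Procrustes mean shape, an orthonormal
#' principal-component basis of the aligned training coordinates, and the
#' PC-score positions of the mean OA (KL 2-4) and mean non-OA (KL 0-1)
#' training shapes, which define the line along which new shapes are scored.
#'
#' @slot bone Bone label.
#' @slot meanShape `nPoints x 3` Procrustes mean (mm, centred at the origin).
#' @slot basis `3*nPoints x M` orthonormal matrix of principal components.
#' @slot eigenvalues Length-M non-increasing variances (mm^2) of the retained
#'   components.
#' @slot mNonOA,mOA Length-M PC-score vectors of the two group mean shapes.
#' @slot nTrainOA,nTrainNonOA Training group sizes.
#' @slot varianceFraction The variance fraction used to truncate the basis.
#' @export
setClass("ShapeModel",
  slots = c(bone = "character", meanShape = "matrix", basis = "matrix",
            eigenvalues = "numeric", mNonOA = "numeric", mOA = "numeric",
            nTrainOA = "integer", nTrainNonOA = "integer",
            varianceFraction = "numeric"))

setValidity("ShapeModel", function(object) {
  msg <- character()
  if (!object@bone %in% BONES) msg <- c(msg, "invalid bone")
  B <- object@basis
  if (nrow(object@meanShape) * 3L != nrow(B))
    msg <- c(msg, "basis rows must equal 3 * nPoints")
  g <- crossprod(B)
  if (max(abs(g - diag(ncol(B)))) > 1e-8)
    msg <- c(msg, "basis columns must be orthonormal (tol 1e-8)")
  ev <- object@eigenvalues
  if (length(ev) != ncol(B)) msg <- c(msg, "eigenvalues length != basis columns")
  if (any(ev < -1e-12)) msg <- c(msg, "eigenvalues must be non-negative")
  if (any(diff(ev) > 1e-8)) msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(object@mOA) != ncol(B) || length(object@mNonOA) != ncol(B))
    msg <- c(msg, "group mean score vectors must have length M")
  if (sqrt(sum((object@mOA - object@mNonOA)^2)) <= 1e-8)
    msg <- c(msg, "degenerate model: OA and non-OA group means coincide")
  if (length(msg)) msg else TRUE
})

#' PsModel: fitted propensity (stratification) score model
#'
#' Logistic regression of case status on the pre-specified baseline
#' covariates (age band, gender, weight category, pain NRS, knee side).
#' KL grade is deliberately not part of the design.
#'
#' @slot coefficients Named coefficient vector.
#' @slot se Named standard errors.
#' @slot logLik Maximized log-likelihood.
#' @slot n Number of knees in the fit.
#' @slot converged Logical.
#' @slot separation Logical; `TRUE` when the fit shows signs of complete or
#'   quasi-complete separation.
#' @export
setClass("PsModel",
  slots = c(coefficients = "numeric", se = "numeric", logLik = "numeric",
            n = "integer", converged = "logical", separation = "logical"))

#' @rdname PsModel-class
#' @param object A `PsModel`.
#' @export
setMethod("coef", "PsModel", function(object) object@coefficients)

#' ClrFit: conditional logistic regression fit for 1:1 matched pairs
#'
#' @slot beta Named coefficient vector.
#' @slot cov Variance-covariance matrix (inverse observed information).
#' @slot logLik Maximized conditional log-likelihood (all supplied pairs;
#'   concordant pairs contribute the constant `log(1/2)`).
#' @slot aic `2k - 2 logLik`.
#' @slot k Number of estimated parameters.
#' @slot nInformative Number of pairs with any within-pair covariate
#'   difference.
#' @slot nPairs Number of pairs supplied to the fit.
#' @slot converged Logical.
#' @export
setClass("ClrFit",
  slots = c(beta = "numeric", cov = "matrix", logLik = "numeric",
            aic = "numeric", k = "integer", nInformative = "integer",
            nPairs = "integer", converged = "logical"))

setValidity("ClrFit", function(object) {
  msg <- character()
  if (length(object@beta) != object@k) msg <- c(msg, "k must equal length(beta)")
  if (abs(object@aic - (2 * object@k - 2 * object@logLik)) > 1e-8)
    msg <- c(msg, "aic must equal 2k - 2 logLik")
  if (length(msg)) msg else TRUE
})
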