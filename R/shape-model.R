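#' Fit the principal-component shape model and OA discriminant vector
#'
#' Rigidly aligns the KL-labelled training shapes (generalized Procrustes,
#' no scaling), takes principal components of the centred aligned coordinate
#' matrix, truncates the basis at the smallest number of components explaining
#' at least `varFrac` of total variance, and records the PC-score positions of
#' the mean OA (KL 2-4) and mean non-OA (KL 0-1) group shapes. The line
#' through those two points is the OA vector on which [scoreShapes()]
#' projects new shapes.
#'
#' Training samples with missing KL grade are excluded (group membership
#' requires a label); both groups must be non-empty and must not coincide.
#'
#' @param shapes A [ShapeSet-class] with KL grades.
#' @param varFrac Variance fraction in (0, 1] at which to truncate the PC
#'   basis. Default 0.98.
#' @param tol,maxIter Passed to [gpaAlign()].
#' @return A [ShapeModel-class].
#' @examples
#' train <- generateTrainingSet(simConfig(nTrain = 24), seed = 7, bone = "femur")
#' fitShapeModel(train)
#' @export
fitShapeModel <- function(shapes, varFrac = 0.98, tol = 1e-7, maxIter = 100L) {
  stopifnot(is(shapes, "ShapeSet"))
  if (!is.numeric(varFrac) || length(varFrac) != 1L || varFrac <= 0 || varFrac > 1)
    stop("varFrac must lie in (0, 1]")
  keep <- !is.na(klGrades(shapes))
  if (any(!keep)) {
    message(sprintf("excluding %d training shape(s) with missing KL grade", sum(!keep)))
    shapes <- shapes[which(keep)]
  }
  kl <- klGrades(shapes)
  isOA <- kl >= 2L
  if (!any(isOA) || !any(!isOA))
    stop("both an OA (KL 2-4) and a non-OA (KL 0-1) training group are required")

  g <- gpaAlign(shapes, tol = tol, maxIter = maxIter)
  X <- flattenShapes(g$shapes)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  n <- nrow(X)
  ev <- sv$d^2 / (n - 1)
  cum <- cumsum(ev) / sum(ev)
  M <- which(cum >= varFrac - 1e-12)[1]
  basis <- sv$v[, seq_len(M), drop = FALSE]
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(M)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  scores <- Xc %*% basis
  mOA <- colMeans(scores[isOA, , drop = FALSE])
  mNonOA <- colMeans(scores[!isOA, , drop = FALSE])
  if (sqrt(sum((mOA - mNonOA)^2)) <= 1e-8)
    stop("degenerate model: OA and non-OA group mean shapes coincide")
  new("ShapeModel", bone = bone(shapes), meanShape = unflattenShape(mu),
      basis = basis, eigenvalues = ev[seq_len(M)], mNonOA = mNonOA, mOA = mOA,
      nTrainOA = sum(isOA), nTrainNonOA = sum(!isOA),
      varianceFraction = varFrac)
}

scoreOne <- function(P, model, align) {
  ref <- model@meanShape
  if (align) P <- alignToReference(P, ref) else P <- centreShape(P)
  x <- as.vector(t(P)) - as.vector(t(ref))
  p <- drop(crossprod(model@basis, x))
  delta <- model@mOA - model@mNonOA
  nd2 <- sum(delta^2)
  raw <- sum((p - model@mNonOA) * delta)  # = (p - mNonOA) . u * ||delta||
  2 * raw / nd2 - 1
}

#' @rdname scoreShapes
#' @aliases scoreShapes,ShapeSet,ShapeModel-method
setMethod("scoreShapes", signature("ShapeSet", "ShapeModel"),
  function(x, model, align = TRUE) {
    if (bone(x) != bone(model))
      stop(sprintf("bone mismatch: shapes are '%s', model is '%s'",
                   bone(x), bone(model)))
    if (nPoints(x) != nPoints(model))
      stop(sprintf("point count mismatch: shapes have %d points, model %d",
                   nPoints(x), nPoints(model)))
    b <- vapply(seq_len(nSamples(x)),
                function(s) scoreOne(x@coords[, , s], model, align),
                numeric(1))
    data.frame(knee_id = kneeIds(x), bone = bone(x), b = b,
               stringsAsFactors = FALSE)
  })

#' @rdname scoreShapes
setMethod("scoreShapes", signature("matrix", "ShapeModel"),
  function(x, model, align = TRUE) {
    if (nrow(x) != nPoints(model) || ncol(x) != 3L)
      stop("matrix input must be nPoints x 3 for this model")
    scoreOne(x, model, align)
  })

#' Reconstruct the shape at a position in PC-score space
#'
#' @param model A [ShapeModel-class].
#' @param p Length-M PC-score vector (e.g. `model@mOA`).
#' @return `nPoints x 3` matrix in the model frame.
#' @export
shapeFromScores <- function(model, p) {
  stopifnot(is(model, "ShapeModel"), length(p) == ncol(model@basis))
  unflattenShape(as.vector(t(model@meanShape)) + drop(model@basis %*% p))
}
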