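#' Optimal rigid rotation (Kabsch)
#'
#' Returns the rotation matrix R (det +1) minimizing ||X R - Y||_F for two
#' centred point sets. No scaling: size differences are preserved.
#'
#' @param X,Y Centred `n x 3` matrices.
#' @return `3 x 3` rotation matrix; apply as `X %*% R`.
#' @keywords internal
kabschRotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

centreShape <- function(P) sweep(P, 2L, colMeans(P))

#' Generalized Procrustes alignment (rigid: translation + rotation only)
#'
#' Iteratively aligns every shape to the running mean shape and re-estimates
#' the mean until it stabilizes. Scaling is deliberately not removed: overall
#' bone enlargement (e.g. osteophytic margin growth) is disease signal that
#' the downstream OA vector must retain.
#'
#' @param shapes A [ShapeSet-class] with at least two samples.
#' @param tol Convergence tolerance on the mean per-point displacement of the
#'   mean shape between iterations (mm). Default `1e-7`.
#' @param maxIter Maximum number of iterations (default 100).
#' @return A list with elements `shapes` (the aligned [ShapeSet-class]),
#'   `meanShape` (`nPoints x 3`, centred), `iterations`, and `converged`.
#' @examples
#' s <- generateTrainingSet(simConfig(nTrain = 12), seed = 1, bone = "tibia")
#' g <- gpaAlign(s)
#' g$converged
#' @export
gpaAlign <- function(shapes, tol = 1e-7, maxIter = 100L) {
  stopifnot(is(shapes, "ShapeSet"))
  n <- nSamples(shapes)
  if (n < 2L) stop("gpaAlign requires at least 2 samples")
  arr <- shapes@coords
  for (s in seq_len(n)) {
    P <- centreShape(arr[, , s])
    if (max(abs(P)) < 1e-12)
      stop(sprintf("degenerate shape '%s': all points coincide", shapes@kneeId[s]))
    arr[, , s] <- P
  }
  # initialize the reference from the coordinate-wise mean: on already-aligned
  # input the first iteration is then a no-op, making alignment idempotent.
  # (A near-degenerate mean from mutually rotated poses falls back to the
  # first shape.)
  m <- apply(arr, c(1, 2), mean)
  scale0 <- mean(sqrt(rowSums(arr[, , 1]^2)))
  if (mean(sqrt(rowSums(m^2))) < 1e-3 * scale0) m <- arr[, , 1]
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    for (s in seq_len(n)) {
      arr[, , s] <- arr[, , s] %*% kabschRotation(arr[, , s], m)
    }
    newM <- centreShape(apply(arr, c(1, 2), mean))
    disp <- mean(sqrt(rowSums((newM - m)^2)))
    m <- newM
    if (disp < tol) { converged <- TRUE; break }
  }
  out <- shapes
  out@coords <- arr
  list(shapes = out, meanShape = m, iterations = iter, converged = converged)
}

#' Rigidly align one point set onto a reference
#'
#' Translation + rotation (Kabsch), no scaling.
#'
#' @param P `n x 3` point matrix.
#' @param ref Centred `n x 3` reference (e.g. a model mean shape).
#' @return The aligned, centred `n x 3` matrix.
#' @export
alignToReference <- function(P, ref) {
  stopifnot(is.matrix(P), is.matrix(ref), all(dim(P) == dim(ref)))
  P <- centreShape(P)
  P %*% kabschRotation(P, ref)
}
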