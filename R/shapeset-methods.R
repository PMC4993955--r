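#' @rdname ShapeSet-class
#' @aliases bone,ShapeSet-method
setMethod("bone", "ShapeSet", function(x) x@bone)

#' @rdname ShapeSet-class
setMethod("bone", "ShapeModel", function(x) x@bone)

#' @rdname ShapeSet-class
setMethod("nPoints", "ShapeSet", function(x) dim(x@coords)[1])

#' @rdname ShapeSet-class
setMethod("nPoints", "ShapeModel", function(x) nrow(x@meanShape))

#' @rdname ShapeSet-class
setMethod("nSamples", "ShapeSet", function(x) dim(x@coords)[3])

#' @rdname ShapeSet-class
setMethod("kneeIds", "ShapeSet", function(x) x@kneeId)

#' @rdname ShapeSet-class
setMethod("klGrades", "ShapeSet", function(x) x@klGrade)

#' @rdname ShapeSet-class
setMethod("shapeCoords", "ShapeSet", function(x, i) {
  if (missing(i)) return(x@coords)
  if (is.character(i)) i <- match(i, x@kneeId)
  x@coords[, , i, drop = length(i) > 1L]
})

#' @rdname ShapeSet-class
#' @param j,drop,... Unused, present for generic compatibility.
#' @export
setMethod("[", "ShapeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@kneeId)
  new("ShapeSet", bone = x@bone, coords = x@coords[, , i, drop = FALSE],
      kneeId = x@kneeId[i], klGrade = x@klGrade[i],
      meta = if (nrow(x@meta)) x@meta[i, , drop = FALSE] else x@meta)
})

setMethod("show", "ShapeSet", function(object) {
  cat(sprintf("ShapeSet: %d %s shape(s), %d corresponded points each\n",
              nSamples(object), object@bone, nPoints(object)))
  kl <- object@klGrade
  if (any(!is.na(kl))) {
    cat("  KL grades:",
        paste(sprintf("%s:%d", names(table(kl, useNA = "ifany")),
                      table(kl, useNA = "ifany")), collapse = " "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf("ShapeModel (%s): %d points, %d principal components (%.0f%% variance)\n",
              object@bone, nPoints(object), ncol(object@basis),
              100 * object@varianceFraction))
  cat(sprintf("  trained on %d OA (KL 2-4) and %d non-OA (KL 0-1) shapes\n",
              object@nTrainOA, object@nTrainNonOA))
  cat(sprintf("  OA-vector length in score space: %.3f\n",
              sqrt(sum((object@mOA - object@mNonOA)^2))))
  invisible(NULL)
})

#' Flatten ShapeSet coordinates to a sample-by-coordinate matrix
#'
#' Row i is sample i as (x1, y1, z1, x2, y2, z2, ...).
#' @param x A [ShapeSet-class].
#' @return A `nSamples x 3*nPoints` matrix.
#' @keywords internal
flattenShapes <- function(x) {
  d <- dim(x@coords)
  out <- matrix(NA_real_, d[3], d[1] * 3L)
  for (s in seq_len(d[3])) out[s, ] <- as.vector(t(x@coords[, , s]))
  rownames(out) <- x@kneeId
  out
}

#' @keywords internal
unflattenShape <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
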