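#' @rdname ShapeSet-class
#' @param x,object A `ShapeSet` or `ShapeModel`.
#' @export
setGeneric("bone", function(x) standardGeneric("bone"))

#' @rdname ShapeSet-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname ShapeSet-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname ShapeSet-class
#' @export
setGeneric("kneeIds", function(x) standardGeneric("kneeIds"))

#' @rdname ShapeSet-class
#' @export
setGeneric("klGrades", function(x) standardGeneric("klGrades"))

#' @rdname ShapeSet-class
#' @param i Sample index (integer, logical or kneeId character vector).
#' @export
setGeneric("shapeCoords", function(x, i) standardGeneric("shapeCoords"))

#' Score shapes on the normalized OA vector scale
#'
#' Projects each shape's PC scores orthogonally onto the line through the
#' mean non-OA and mean OA training shapes and rescales so those group means
#' score exactly -1 and +1.
#'
#' @param x A [ShapeSet-class] (or a single `nPoints x 3` matrix).
#' @param model A [ShapeModel-class] for the same bone and point count.
#' @param align Rigidly align (translation + rotation, no scaling) each shape
#'   to the model mean before projecting. Default `TRUE`; set `FALSE` only if
#'   the input is already expressed in the model frame.
#' @return A `data.frame` with columns `knee_id`, `bone`, `b` (the normalized
#'   shape vector value).
#' @export
setGeneric("scoreShapes", function(x, model, align = TRUE)
  standardGeneric("scoreShapes"))

#' @rdname ClrFit-class
#' @param fit A `ClrFit`.
#' @param level Confidence level for the Wald intervals.
#' @export
setGeneric("oddsRatios", function(fit, level = 0.95) standardGeneric("oddsRatios"))
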