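#' Smallest detectable difference from test-retest measurements
#'
#' The 95% Bland-Altman limit on test-retest agreement:
#' `1.96 * sd(test - retest)`. This is the measurement noise floor of the
#' shape vector score; a longitudinal change smaller than the SDD cannot be
#' distinguished from repeat-scan variability.
#'
#' @param test,retest Equal-length numeric vectors of paired scores
#'   (normalized shape-vector units), `n >= 2`.
#' @return The SDD (same units as the scores).
#' @examples
#' smallestDetectableDifference(c(0.1, 0.5, 0.9), c(0.2, 0.45, 0.95))
#' @export
smallestDetectableDifference <- function(test, retest) {
  if (!is.numeric(test) || !is.numeric(retest) || length(test) != length(retest))
    stop("test and retest must be equal-length numeric vectors")
  if (length(test) < 2L) stop("at least 2 paired measurements are required")
  if (any(!is.finite(test)) || any(!is.finite(retest)))
    stop("scores must be finite")
  1.96 * stats::sd(test - retest)
}
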