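#' Paired t-test on matched case/control values
#'
#' Computed from the textbook formulas on the within-pair differences
#' `d_i = case_i - control_i`: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `n - 1` degrees of freedom and a symmetric 95% CI. A zero difference SD
#' (e.g. case equal to control in every pair) is returned as a degenerate
#' result with `t` and `p` set to `NA` rather than an error.
#'
#' @param caseValues,controlValues Equal-length numeric vectors, `n >= 2`,
#'   pair-aligned.
#' @param level Confidence level (default 0.95).
#' @return A list: `mean_diff`, `ci` (length 2), `t`, `df`, `p`,
#'   `degenerate`.
#' @examples
#' pairedT(c(2, 3, 4), c(1, 1, 1))
#' @export
pairedT <- function(caseValues, controlValues, level = 0.95) {
  if (length(caseValues) != length(controlValues))
    stop("paired samples must have equal length")
  n <- length(caseValues)
  if (n < 2L) stop("at least 2 pairs are required")
  if (any(!is.finite(caseValues)) || any(!is.finite(controlValues)))
    stop("values must be finite")
  d <- caseValues - controlValues
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    return(list(mean_diff = m, ci = c(m, m), t = NA_real_, df = df,
                p = NA_real_, degenerate = TRUE))
  }
  sem <- s / sqrt(n)
  tval <- m / sem
  half <- stats::qt(1 - (1 - level) / 2, df) * sem
  list(mean_diff = m, ci = c(m - half, m + half), t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df), degenerate = FALSE)
}

#' Assign tertiles of a score distribution
#'
#' Cut points are the 1/3 and 2/3 empirical quantiles of the pooled baseline
#' scores (cases and matched controls together). Intervals are lower-open /
#' upper-closed with the lowest interval closed, so values tied with a cut
#' point fall in the lower tertile. The highest tertile contains scores
#' closest to the mean OA shape (+1 side), the lowest those closest to the
#' mean non-OA shape (-1 side).
#'
#' @param scores Numeric vector with at least 3 distinct values.
#' @return A list: `cut_points` (q33, q67) and `labels` (factor
#'   `lowest`/`middle`/`highest`, same length as `scores`).
#' @export
assignTertiles <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(scores)) < 3L)
    stop("at least 3 distinct score values are required for tertiles")
  q <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
  if (q[1] >= q[2])
    stop("degenerate tertile cut points (heavy ties in scores)")
  labels <- cut(scores, c(-Inf, q, Inf),
                labels = c("lowest", "middle", "highest"), right = TRUE)
  list(cut_points = q, labels = labels)
}

#' Indicator (dummy) columns for tertile membership
#'
#' Lowest tertile is the reference.
#'
#' @param labels Factor from [assignTertiles()].
#' @return `n x 2` matrix with columns `middle`, `highest`.
#' @export
tertileDummies <- function(labels) {
  cbind(middle = as.numeric(labels == "middle"),
        highest = as.numeric(labels == "highest"))
}

#' KL-grade dummy columns (KL 0 reference)
#'
#' @param kl Integer KL grades 0-4 (no missing values).
#' @return `n x 4` matrix with columns `kl1`..`kl4`.
#' @export
klDummies <- function(kl) {
  if (any(is.na(kl))) stop("KL grades must be non-missing (drop those pairs first)")
  out <- sapply(1:4, function(g) as.numeric(kl == g))
  colnames(out) <- paste0("kl", 1:4)
  out
}
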