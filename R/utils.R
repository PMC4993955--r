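#' Derive a deterministic child seed
#'
#' Stages of a pipeline run (cohort generation, matching tie-breaks, per-knee
#' shape noise, ...) each get their own RNG stream derived from one master
#' seed, so a stage can be re-run in isolation and still reproduce exactly.
#'
#' @param seed Master seed (integer-valued).
#' @param tag Character tag naming the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(tag), length(tag) == 1L)
  m <- 2147483629  # large prime < 2^31
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded package internals never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}
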