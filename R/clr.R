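#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the exact conditional likelihood for 1:1 matched sets,
#' `L(beta) = prod_i exp(x_case_i beta) / (exp(x_case_i beta) + exp(x_control_i beta))`,
#' by Newton-Raphson from `beta = 0` with step halving; convergence when the
#' maximum absolute score falls below `tol`. Pairs whose case and control
#' covariates are identical carry no information about `beta` (they
#' contribute the constant `log(1/2)`) and are counted separately. Monotone
#' likelihoods (e.g. all informative pairs concordant in sign for a binary
#' covariate) are detected and reported as an error rather than returning a
#' silently huge coefficient.
#'
#' Wald standard errors come from the inverse observed information at the
#' maximum; `AIC = 2k - 2 logLik`.
#'
#' @param xCase,xControl Numeric matrices (`n_pairs x k`, or vectors for
#'   `k = 1`) of case and control covariates, aligned row-wise by pair.
#' @param terms Covariate names (defaults to `colnames(xCase)`).
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @param maxIter Maximum Newton iterations (default 50).
#' @return A [ClrFit-class].
#' @examples
#' # binary exposure: 20 case-only-exposed vs 10 control-only-exposed
#' # discordant pairs; the CLR odds ratio is their ratio, 2.0
#' fit <- fitClr(c(rep(1, 20), rep(0, 10)), c(rep(0, 20), rep(1, 10)))
#' exp(fit@beta)
#' @export
fitClr <- function(xCase, xControl, terms = NULL, tol = 1e-8, maxIter = 50L) {
  if (is.vector(xCase)) xCase <- matrix(xCase, ncol = 1L)
  if (is.vector(xControl)) xControl <- matrix(xControl, ncol = 1L)
  if (!all(dim(xCase) == dim(xControl)))
    stop("xCase and xControl must have identical dimensions")
  if (any(!is.finite(xCase)) || any(!is.finite(xControl)))
    stop("covariates must be finite (drop pairs with missing values first)")
  n <- nrow(xCase); k <- ncol(xCase)
  if (n < 1L) stop("at least one pair is required")
  terms <- terms %||% colnames(xCase) %||% sprintf("x%d", seq_len(k))
  d <- xCase - xControl
  informative <- rowSums(abs(d)) > 0
  nInf <- sum(informative)
  if (nInf == 0L)
    stop("no informative pairs: every pair has identical case and control covariates")

  logLikFn <- function(beta) sum(stats::plogis(drop(d %*% beta), log.p = TRUE))
  beta <- rep(0, k)
  ll <- logLikFn(beta)
  converged <- FALSE
  info <- NULL
  for (iter in seq_len(maxIter)) {
    eta <- drop(d %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(d, 1 - p))
    w <- p * (1 - p)
    info <- crossprod(d * w, d)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step))
      stop("singular information matrix: covariates collinear within pairs or likelihood monotone")
    # step halving to guarantee ascent
    s <- 1
    repeat {
      cand <- beta + s * step
      llNew <- logLikFn(cand)
      if (llNew >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-8) stop("conditional likelihood maximization failed to make progress")
    }
    beta <- cand; ll <- llNew
    if (max(abs(beta)) > 30)
      stop("divergent fit: monotone conditional likelihood (complete separation of discordant pairs); no finite estimate exists")
  }
  if (!converged)
    stop(sprintf("conditional logistic regression did not converge in %d iterations", maxIter))
  cov <- solve(info)
  # a vanishing gradient at an extreme estimate is divergence, not convergence:
  # with a monotone conditional likelihood the score tends to 0 as beta runs
  # to infinity, so the estimate and its Wald variance must also be inspected
  if (any(abs(beta) > 15) || any(!is.finite(cov)) || any(diag(cov) > 1e4))
    stop("divergent fit: monotone conditional likelihood (complete separation of discordant pairs); no finite estimate exists")
  names(beta) <- terms
  dimnames(cov) <- list(terms, terms)
  new("ClrFit", beta = beta, cov = cov, logLik = ll,
      aic = 2 * k - 2 * ll, k = as.integer(k),
      nInformative = as.integer(nInf), nPairs = as.integer(n),
      converged = TRUE)
}

#' @rdname ClrFit-class
#' @aliases oddsRatios,ClrFit-method
setMethod("oddsRatios", "ClrFit", function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit@cov))
  data.frame(term = names(fit@beta),
             beta = unname(fit@beta),
             se = unname(se),
             or = exp(unname(fit@beta)),
             or_low = exp(unname(fit@beta) - z * se),
             or_high = exp(unname(fit@beta) + z * se),
             p = 2 * stats::pnorm(-abs(unname(fit@beta) / se)),
             stringsAsFactors = FALSE)
})

#' @rdname ClrFit-class
#' @export
setMethod("coef", "ClrFit", function(object) object@beta)

#' @rdname ClrFit-class
#' @export
setMethod("vcov", "ClrFit", function(object) object@cov)

#' @rdname ClrFit-class
#' @export
setMethod("logLik", "ClrFit", function(object) object@logLik)

setMethod("show", "ClrFit", function(object) {
  cat(sprintf("ClrFit: %d pairs (%d informative), k = %d, logLik = %.3f, AIC = %.3f\n",
              object@nPairs, object@nInformative, object@k,
              object@logLik, object@aic))
  print(oddsRatios(object), digits = 4)
  invisible(NULL)
})

#' Rank conditional logistic fits by AIC
#'
#' Compares models fitted on the identical matched-pair sample; fits on
#' different pair counts are refused, which guards against the classic
#' pitfall of comparing AICs across complete-case samples that differ
#' because of missing adjustment covariates (e.g. missing KL grades).
#'
#' @param fits Named list of [ClrFit-class] objects.
#' @return A `data.frame` (`model`, `k`, `logLik`, `AIC`, `deltaAIC`) in
#'   ascending AIC order.
#' @export
compareAic <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, is, logical(1), "ClrFit")))
  nm <- names(fits) %||% sprintf("model%d", seq_along(fits))
  np <- vapply(fits, slot, integer(1), "nPairs")
  if (length(unique(np)) != 1L)
    stop("fits use different pair samples (n = ",
         paste(unique(np), collapse = ", "),
         "); refit all models on a common complete-case pair set")
  out <- data.frame(model = nm,
                    k = vapply(fits, slot, integer(1), "k"),
                    logLik = vapply(fits, slot, numeric(1), "logLik"),
                    AIC = vapply(fits, slot, numeric(1), "aic"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$AIC), ]
  out$deltaAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

#' Conditional logistic fits stratified by a per-pair factor
#'
#' Partitions pairs by a stratifier defined on the case knee (e.g. case KL
#' grade, or time-to-surgery band) and fits the model within each stratum.
#' Strata with no pairs, no informative pairs, or a divergent likelihood are
#' skipped with a log entry; small strata (< `minInformative` informative
#' pairs) are flagged as wide-CI.
#'
#' @param xCase,xControl Covariate matrices as in [fitClr()].
#' @param strata Factor (or vector) of length `n_pairs`, the case knee's
#'   stratum.
#' @param minInformative Informative-pair count under which a stratum is
#'   flagged (default 10).
#' @return A list: `fits` (named list of [ClrFit-class]), `flagged`
#'   (character vector of wide-CI strata), `log` (`data.frame` of skipped
#'   strata and reasons).
#' @export
stratifiedClr <- function(xCase, xControl, strata, minInformative = 10L) {
  if (is.vector(xCase)) xCase <- matrix(xCase, ncol = 1L)
  if (is.vector(xControl)) xControl <- matrix(xControl, ncol = 1L)
  if (length(strata) != nrow(xCase))
    stop("strata must be defined for every pair")
  strata <- as.factor(strata)
  fits <- list(); flagged <- character()
  log <- data.frame(stratum = character(), reason = character(),
                    stringsAsFactors = FALSE)
  for (lev in levels(strata)) {
    i <- which(strata == lev)
    if (!length(i)) {
      log <- rbind(log, data.frame(stratum = lev, reason = "empty"))
      next
    }
    fit <- tryCatch(fitClr(xCase[i, , drop = FALSE], xControl[i, , drop = FALSE]),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      log <- rbind(log, data.frame(stratum = lev, reason = fit))
      next
    }
    if (fit@nInformative < minInformative) flagged <- c(flagged, lev)
    fits[[lev]] <- fit
  }
  list(fits = fits, flagged = flagged, log = log)
}
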