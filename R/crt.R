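#' LASSO screening of candidate mediators
#'
#' Cross-validated LASSO regression of the outcome on treatment, covariates
#' and all taxa, with treatment and covariates unpenalized. The screened set
#' `D` collects the taxa with nonzero coefficients at the CV-minimum
#' penalty; the mediation tests are then run conditional on `D`. An empty
#' `D` is valid and yields zero discoveries.
#'
#' @param Y numeric outcome vector.
#' @param treatment 0/1 treatment vector.
#' @param M samples-by-taxa count matrix.
#' @param covariates optional covariate matrix.
#' @param nFolds cross-validation folds (default 10); requires
#'   `n >= 2 * nFolds`.
#' @return list with elements `D` (ordered taxon indices), `lambdaChosen`,
#'   `nFolds`.
#' @export
screenMediators <- function(Y, treatment, M, covariates = NULL,
                            nFolds = 10L) {
  Y <- as.numeric(Y)
  if (sd(Y) == 0) stop("outcome is constant")
  M <- as.matrix(M)
  n <- length(Y)
  if (n < 2 * nFolds)
    stop("need n >= 2 * nFolds for cross-validation")
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  q <- if (is.null(X)) 0L else ncol(X)
  x <- cbind(treatment = as.numeric(treatment), X, M)
  pf <- c(rep(0, 1 + q), rep(1, ncol(M)))
  cvfit <- glmnet::cv.glmnet(x, Y, nfolds = nFolds, penalty.factor = pf,
                             standardize = TRUE)
  beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]  # drop intercept
  betaM <- beta[(1 + q + 1):length(beta)]
  list(D = which(betaM != 0), lambdaChosen = cvfit$lambda.min,
       nFolds = as.integer(nFolds))
}

#' Distill the outcome against all mediators but one
#'
#' Cross-validated LASSO fit of `Y` on treatment, covariates and all taxa
#' except taxon `j` (treatment and covariates unpenalized), returning the
#' in-sample fitted values. With a single taxon the complement is empty and
#' an ordinary regression on treatment and covariates is used.
#'
#' @inheritParams screenMediators
#' @param j index of the taxon excluded from the fit.
#' @return numeric fitted vector of length `n`.
#' @export
distillOutcome <- function(Y, treatment, M, j, covariates = NULL,
                           nFolds = 10L) {
  Y <- as.numeric(Y)
  M <- as.matrix(M)
  stopifnot(j >= 1, j <= ncol(M))
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  q <- if (is.null(X)) 0L else ncol(X)
  Mrest <- M[, -j, drop = FALSE]
  base <- cbind(`(Intercept)` = 1, treatment = as.numeric(treatment), X)
  if (ncol(Mrest) == 0)
    return(as.numeric(base %*% lm.fit(base, Y)$coefficients))
  x <- cbind(base[, -1, drop = FALSE], Mrest)
  pf <- c(rep(0, 1 + q), rep(1, ncol(Mrest)))
  cvfit <- glmnet::cv.glmnet(x, Y, nfolds = nFolds, penalty.factor = pf,
                             standardize = TRUE)
  as.numeric(predict(cvfit, newx = x, s = "lambda.min"))
}

#' Distilled CRT test statistic
#'
#' The normalized absolute inner product of the outcome and mediator
#' residuals,
#' \eqn{|(Y - \hat Y)^\top (M_j - \hat M_j)| / \|M_j - \hat M_j\|_2}.
#'
#' @param y,yhat outcome vector and its distilled fit.
#' @param m,mhat mediator vector and its fitted conditional mean.
#' @return non-negative scalar.
#' @export
crtStatistic <- function(y, yhat, m, mhat) {
  stopifnot(length(y) == length(yhat), length(m) == length(mhat),
            length(y) == length(m))
  rm <- m - mhat
  nrm <- sqrt(sum(rm^2))
  if (nrm == 0)
    stopWithClass("crtDegenerateError",
                  "mediator residual has zero norm; statistic undefined")
  abs(sum((y - yhat) * rm)) / nrm
}

# randomization p-value from an observed statistic and resampled statistics;
# ties count as exceedances (>=), giving the finite-sample floor 1/(B+1)
crtPvalue <- function(statObs, statResamples) {
  B <- length(statResamples)
  (1 + sum(statResamples >= statObs)) / (B + 1)
}

#' Zero-inflated distilled CRT p-value for one taxon
#'
#' Draws `B` mediator resamples from the fitted ZINB model, refits the ZINB
#' regression to each resample to obtain its fitted conditional mean
#' `(1 - pi) * lambda`, computes the [crtStatistic()] for the observed and
#' resampled mediators, and returns
#' `p1 = (1 + #\{b: stat_b >= stat_obs\}) / (B + 1)`.
#'
#' Resample refits that fail fall back to the original fitted mean and are
#' counted; a failure rate above 20% flags the taxon. A degenerate observed
#' mediator residual yields `p1 = 1` with a flag.
#'
#' @param Y outcome vector.
#' @param yhat distilled outcome fit (from [distillOutcome()]).
#' @param mj observed counts of the taxon.
#' @param fit the taxon's [ZinbFit-class].
#' @param treatment,covariates,offset design of the mediator model, reused
#'   when refitting resamples.
#' @param B number of resamples (default 100).
#' @param keepStats return the observed and resampled statistics?
#' @return list with `p1`, `nFail`, `flags`, and (if `keepStats`)
#'   `statObs`, `stats`.
#' @export
zidcrtPvalue <- function(Y, yhat, mj, fit, treatment, covariates = NULL,
                         offset = NULL, B = 100L, keepStats = FALSE) {
  stopifnot(is(fit, "ZinbFit"), B >= 1)
  statObs <- tryCatch(crtStatistic(Y, yhat, mj, fit@fittedMean),
                      error = function(e) {
                        if (inherits(e, "crtDegenerateError")) NULL
                        else stop(e)
                      })
  if (is.null(statObs))
    return(list(p1 = 1, nFail = 0L, flags = "degenerate-residual"))
  warm <- if (fit@method == "zinb")
    c(fit@gamma, fit@alpha, log(fit@phi)) else NULL
  stats <- numeric(B)
  nFail <- 0L
  for (b in seq_len(B)) {
    mb <- sampleZinb(fit)
    refit <- tryCatch(
      fitZinb(mb, treatment, covariates = covariates, offset = offset,
              start = warm, hessian = FALSE),
      error = function(e) NULL)
    if (is.null(refit)) {
      nFail <- nFail + 1L
      mhatB <- fit@fittedMean
    } else mhatB <- refit@fittedMean
    stats[b] <- tryCatch(crtStatistic(Y, yhat, mb, mhatB),
                         error = function(e) 0)
  }
  flags <- character(0)
  if (nFail > 0.2 * B) flags <- c(flags, "resample-refit-failures")
  out <- list(p1 = crtPvalue(statObs, stats), nFail = nFail, flags = flags)
  if (keepStats) { out$statObs <- statObs; out$stats <- stats }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, applied
#' across the tested taxon set. Thin wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bhAdjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}
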