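#' @describeIn runMediation full pipeline on a [MediationExperiment-class]:
#'   optional LASSO screen, then per screened taxon a ZINB fit, outcome
#'   distillation, zero-inflated distilled CRT p-value `p1`, 2-df Wald
#'   p-value `p2`, joint-significance `pmax = max(p1, p2)`, BH adjustment
#'   across the tested set, selection at `pAdj < fdr`, and effect
#'   estimation (with optional bootstrap CIs) for the selected taxa.
#'   Deterministic given `seed`; taxa are independent work units with
#'   per-taxon RNG streams, so results do not depend on execution order.
#'
#' @param B number of CRT resamples (default 100).
#' @param fdr FDR threshold for selection (default 0.05).
#' @param seed integer master seed.
#' @param screen apply the LASSO screening step first? (default TRUE)
#' @param nFolds cross-validation folds for the LASSO steps.
#' @param offset `"auto"` (per-sample `logDepth` column when present, else
#'   log library size), `"libsize"`, `"none"`, or a numeric vector.
#' @param ci compute bootstrap CIs for the selected taxa?
#' @param ciReps bootstrap repetitions (default 1000).
#' @param ciLevel confidence level (default 0.95).
#' @export
setMethod("runMediation", "MediationExperiment",
  function(x, B = 100L, fdr = 0.05, seed = 1L, screen = TRUE,
           nFolds = 10L, offset = "auto", ci = FALSE, ciReps = 1000L,
           ciLevel = 0.95) {
    mediationPipeline(
      Y = outcome(x), treatment = treatment(x),
      M = t(assay(x, "counts")), covariates = covariateMatrix(x),
      offset = resolveOffset(x, offset), B = B, fdr = fdr, seed = seed,
      screen = screen, nFolds = nFolds, naive = FALSE, ci = ci,
      ciReps = ciReps, ciLevel = ciLevel)
  })

#' @describeIn runNaiveMediation same pipeline, but each mediator is
#'   modelled as Gaussian on the `log(count + 1)` scale: resamples are drawn
#'   from the fitted normal, and the treatment-mediator test is the 1-df
#'   Wald test on the Gaussian slope. Serves as the normality-based
#'   baseline that ignores zero inflation.
#' @param B,fdr,seed,screen,nFolds as in the full pipeline.
#' @export
setMethod("runNaiveMediation", "MediationExperiment",
  function(x, B = 100L, fdr = 0.05, seed = 1L, screen = TRUE,
           nFolds = 10L) {
    mediationPipeline(
      Y = outcome(x), treatment = treatment(x),
      M = t(assay(x, "counts")), covariates = covariateMatrix(x),
      offset = NULL, B = B, fdr = fdr, seed = seed, screen = screen,
      nFolds = nFolds, naive = TRUE, ci = FALSE, ciReps = 0L,
      ciLevel = 0.95)
  })

resolveOffset <- function(x, offset) {
  if (is.numeric(offset)) return(offset)
  mode <- match.arg(offset, c("auto", "libsize", "none"))
  if (mode == "auto")
    mode <- if (!is.null(logDepth(x))) "depth" else "libsize"
  switch(mode,
         depth = logDepth(x),
         libsize = log(pmax(colSums(assay(x, "counts")), 1)),
         none = NULL)
}

# core pipeline on plain vectors/matrices (samples-by-taxa M)
mediationPipeline <- function(Y, treatment, M, covariates, offset,
                              B, fdr, seed, screen, nFolds, naive,
                              ci, ciReps, ciLevel) {
  Y <- as.numeric(Y)
  tr <- as.numeric(treatment)
  M <- as.matrix(M)
  n <- length(Y)
  m <- ncol(M)
  stopifnot(nrow(M) == n, length(tr) == n, B >= 1, fdr > 0, fdr < 1)
  if (length(unique(tr)) < 2)
    stop("treatment must have both levels present")
  taxa <- if (!is.null(colnames(M))) colnames(M) else paste0("taxon", 1:m)

  set.seed(seed)
  scr <- if (screen)
    screenMediators(Y, tr, M, covariates = covariates, nFolds = nFolds)
  else list(D = seq_len(m), lambdaChosen = NULL, nFolds = as.integer(nFolds))
  D <- scr$D

  rows <- vector("list", length(D))
  fits <- list()
  for (k in seq_along(D)) {
    j <- D[k]
    row <- data.frame(taxon = taxa[j], index = j, p1 = NA_real_,
                      p2 = NA_real_, pmax = NA_real_, pAdj = NA_real_,
                      selected = FALSE, flags = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch(
      testOneTaxon(Y, tr, M, covariates, offset, j, B, nFolds, naive,
                   seed),
      error = function(e) list(flags = paste0("untestable: ",
                                              conditionMessage(e))))
    if (!is.null(res$p1)) {
      row$p1 <- res$p1; row$p2 <- res$p2
      row$pmax <- max(res$p1, res$p2)
      if (!is.null(res$fit)) fits[[as.character(j)]] <- res$fit
    }
    row$flags <- paste(res$flags, collapse = "; ")
    rows[[k]] <- row
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), index = integer(0), p1 = numeric(0),
               p2 = numeric(0), pmax = numeric(0), pAdj = numeric(0),
               selected = logical(0), flags = character(0))
  tested <- which(!is.na(results$pmax))
  if (length(tested)) {
    results$pAdj[tested] <- bhAdjust(results$pmax[tested])
    results$selected <- !is.na(results$pAdj) & results$pAdj < fdr
  }

  effects <- NULL
  selIdx <- results$index[results$selected]
  for (col in c("nie", "niep", "niea"))
    results[[col]] <- rep(NA_real_, nrow(results))
  if (length(selIdx) && !naive) {
    effects <- tryCatch(
      estimateEffects(Y, tr, M, selIdx, covariates = covariates,
                      offset = offset, fits = fits),
      error = function(e) NULL)
    if (!is.null(effects)) {
      ord <- match(effects@table$taxon, results$index)
      results[ord, c("nie", "niep", "niea")] <-
        effects@table[, c("nie", "niep", "niea")]
      if (ci && ciReps > 0) {
        for (col in c("nieLower", "nieUpper", "niepLower", "niepUpper",
                      "nieaLower", "nieaUpper")) results[[col]] <- NA_real_
        for (j in selIdx) {
          set.seed(deriveSeed(seed, 500000L + j))
          cij <- tryCatch(
            effectCI(Y, tr, M, taxon = j, selected = selIdx,
                     covariates = covariates, nRep = ciReps,
                     level = ciLevel, offset = offset),
            error = function(e) NULL)
          if (is.null(cij)) next
          r <- match(j, results$index)
          results[r, c("nieLower", "nieUpper")] <- cij[1, c("lower", "upper")]
          results[r, c("niepLower", "niepUpper")] <- cij[2, c("lower", "upper")]
          results[r, c("nieaLower", "nieaUpper")] <- cij[3, c("lower", "upper")]
        }
      }
    }
  }

  new("MediationResults", results = results,
      screen = scr,
      config = list(B = as.integer(B), fdr = fdr, seed = as.integer(seed),
                    screen = screen, nFolds = as.integer(nFolds),
                    ci = ci, ciReps = as.integer(ciReps),
                    ciLevel = ciLevel, n = n, m = m),
      effects = effects, method = if (naive) "gaussian" else "zinb")
}

# test a single screened taxon; reproducible via its own RNG stream
testOneTaxon <- function(Y, tr, M, covariates, offset, j, B, nFolds,
                         naive, seed) {
  set.seed(deriveSeed(seed, j))
  mj <- M[, j]
  flags <- character(0)
  if (all(mj == 0))
    stopWithClass("zinbDegenerateError", "all counts zero")
  yhat <- distillOutcome(Y, tr, M, j, covariates = covariates,
                         nFolds = nFolds)
  if (naive) return(c(testOneTaxonGaussian(Y, yhat, mj, tr, covariates, B),
                      list(fit = NULL)))
  fit <- fitZinb(mj, tr, covariates = covariates, offset = offset)
  flags <- c(flags, fit@flags)
  if (!fit@converged) flags <- c(flags, "non-convergent-fit")
  crt <- zidcrtPvalue(Y, yhat, mj, fit, tr, covariates = covariates,
                      offset = offset, B = B)
  wald <- waldTest(fit)  # throws zinbSingularError -> taxon untestable
  list(p1 = crt$p1, p2 = wald$p, fit = fit,
       flags = c(flags, crt$flags))
}

# Gaussian dCRT on log(count + 1): linear mediator model, normal resamples
testOneTaxonGaussian <- function(Y, yhat, mj, tr, covariates, B) {
  z <- log1p(mj)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  D <- cbind(1, tr, X)
  fit <- lm.fit(D, z)
  zhat <- as.numeric(D %*% fit$coefficients)
  dfres <- length(z) - ncol(D)
  sigma2 <- sum(fit$residuals^2) / dfres
  XtXinv <- solve(crossprod(D))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  w2 <- (fit$coefficients[2] / se)^2
  p2 <- pchisq(w2, df = 1, lower.tail = FALSE)
  statObs <- tryCatch(crtStatistic(Y, yhat, z, zhat),
                      error = function(e) NULL)
  if (is.null(statObs))
    return(list(p1 = 1, p2 = p2, flags = "degenerate-residual"))
  stats <- numeric(B)
  for (b in seq_len(B)) {
    zb <- zhat + rnorm(length(z), 0, sqrt(sigma2))
    fitb <- lm.fit(D, zb)
    stats[b] <- crtStatistic(Y, yhat, zb, as.numeric(D %*% fitb$coefficients))
  }
  list(p1 = crtPvalue(statObs, stats), p2 = unname(p2), flags = character(0))
}

#' @rdname MediationResults-class
#' @export
setMethod("resultsTable", "MediationResults", function(x) x@results)

#' @describeIn MediationResults-class indices of the selected taxa.
#' @export
setMethod("selectedTaxa", "MediationResults", function(x) {
  x@results$index[x@results$selected]
})

#' Logical selection vector over all taxa
#'
#' Maps a [MediationResults-class] onto a logical vector of length `m`
#' (taxa outside the screened set are `FALSE`), as scored by
#' [confusionCounts()].
#'
#' @param x a `MediationResults`.
#' @param m total number of taxa.
#' @return logical vector of length `m`.
#' @export
selectionVector <- function(x, m) {
  stopifnot(is(x, "MediationResults"))
  out <- logical(m)
  out[x@results$index[x@results$selected]] <- TRUE
  out
}

setMethod("show", "MediationResults", function(object) {
  r <- object@results
  cat(sprintf("MediationResults (%s): %d taxa in screened set, %d tested, %d selected at FDR %.2g\n",
              object@method, nrow(r), sum(!is.na(r$pmax)),
              sum(r$selected), object@config$fdr))
  if (sum(r$selected)) {
    cols <- intersect(c("taxon", "p1", "p2", "pmax", "pAdj",
                        "nie", "niep", "niea"), colnames(r))
    print(r[r$selected, cols], row.names = FALSE, digits = 4)
  }
})
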