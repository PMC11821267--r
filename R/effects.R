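#' Decompose a taxon's natural indirect effect
#'
#' For a taxon with outcome-model coefficient `betaM`, count-model
#' coefficients `(alpha0, alpha1, alphaX)` and zero-model coefficients
#' `(gamma0, gamma1, gammaX)`, evaluated at covariate profile `x`, the
#' natural indirect effect is
#' \deqn{NIE = \beta_m \left\{ \frac{e^{a_1}}{1 + e^{g_1}} -
#'   \frac{e^{a_0}}{1 + e^{g_0}} \right\}}
#' with \eqn{a_t = \alpha_0 + t\alpha_1 + \alpha_x^\top x} and
#' \eqn{g_t = \gamma_0 + t\gamma_1 + \gamma_x^\top x}. It splits exactly into
#' a presence-absence part (NIEP, transmitted by the structural-zero
#' indicator) and an abundance part (NIEA):
#' \deqn{NIEP = \beta_m \left\{ \frac{e^{a_1}}{1 + e^{g_1}} -
#'   \frac{e^{a_1}}{1 + e^{g_0}} \right\}, \quad
#'   NIEA = \beta_m \left\{ \frac{e^{a_1}}{1 + e^{g_0}} -
#'   \frac{e^{a_0}}{1 + e^{g_0}} \right\}.}
#' Evaluation is overflow-safe (log-space).
#'
#' @param betaM outcome-model coefficient of the taxon.
#' @param alpha0,alpha1 count-model intercept and treatment coefficient.
#' @param gamma0,gamma1 zero-model intercept and treatment coefficient
#'   (`gamma0 = -Inf` encodes a taxon with no structural zeros).
#' @param alphaX,gammaX optional covariate coefficient vectors.
#' @param x covariate profile at which effects are evaluated (default: none).
#' @return named numeric `c(nie, niep, niea)` with `nie == niep + niea`.
#' @examples
#' nieComponents(2, alpha0 = -1, alpha1 = -2, gamma0 = 0.5, gamma1 = -2)
#' @export
nieComponents <- function(betaM, alpha0, alpha1, gamma0, gamma1,
                          alphaX = numeric(0), gammaX = numeric(0),
                          x = numeric(0)) {
  stopifnot(length(alphaX) == length(x), length(gammaX) == length(x))
  ax <- if (length(x)) sum(alphaX * x) else 0
  gx <- if (length(x)) sum(gammaX * x) else 0
  la1 <- alpha0 + alpha1 + ax
  la0 <- alpha0 + ax
  lg1 <- gamma0 + gamma1 + gx
  lg0 <- gamma0 + gx
  m11 <- exp(la1 - log1pexp(lg1))  # E[M | T=1 pathway on both parts]
  m10 <- exp(la1 - log1pexp(lg0))  # abundance at T=1, presence at T=0
  m00 <- exp(la0 - log1pexp(lg0))
  c(nie = betaM * (m11 - m00),
    niep = betaM * (m11 - m10),
    niea = betaM * (m10 - m00))
}

#' Total natural indirect effect
#'
#' The overall NIE is the sum of the per-taxon effects.
#'
#' @param nie numeric vector of per-taxon NIE values.
#' @return their sum (0 for an empty vector).
#' @export
totalNie <- function(nie) sum(nie)

#' Estimate mediation effects for a selected taxon set
#'
#' Fits the unpenalized outcome regression of `Y` on treatment, covariates
#' and the selected taxa, fits (or reuses) the per-taxon ZINB regressions,
#' and evaluates the NIE decomposition at a covariate profile. The natural
#' direct effect is the outcome-model treatment coefficient.
#'
#' @param Y numeric outcome vector.
#' @param treatment 0/1 treatment vector with both levels present.
#' @param M samples-by-taxa count matrix.
#' @param selected indices of taxa entering the outcome model (non-empty).
#' @param covariates optional covariate matrix.
#' @param xProfile covariate profile for effect evaluation; default the
#'   reference (zero) profile.
#' @param offset optional count-model offset (log depth).
#' @param fits optional named list of pre-computed [ZinbFit-class] objects,
#'   keyed by taxon index as character.
#' @return a [MediationEffects-class].
#' @export
estimateEffects <- function(Y, treatment, M, selected, covariates = NULL,
                            xProfile = NULL, offset = NULL, fits = NULL) {
  tr <- as.numeric(treatment)
  if (length(unique(tr)) < 2)
    stop("treatment is constant: no treatment contrast")
  if (!length(selected)) stop("selected taxon set is empty")
  M <- as.matrix(M)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  q <- if (is.null(X)) 0L else ncol(X)
  if (is.null(xProfile)) xProfile <- numeric(q)
  Msel <- M[, selected, drop = FALSE]
  selNames <- if (!is.null(colnames(M))) colnames(M)[selected] else
    paste0("taxon", selected)
  colnames(Msel) <- selNames
  design <- cbind(`(Intercept)` = 1, treatment = tr, X, Msel)
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    dropped <- setdiff(colnames(design),
                       colnames(design)[qrD$pivot[seq_len(qrD$rank)]])
    stop("outcome design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(design, as.numeric(Y))
  beta <- fit$coefficients
  res <- fit$residuals
  sigma2 <- sum(res^2) / (length(Y) - ncol(design))
  betaM <- beta[selNames]
  tab <- data.frame(taxon = selected, nie = NA_real_, niep = NA_real_,
                    niea = NA_real_)
  for (k in seq_along(selected)) {
    j <- selected[k]
    zf <- if (!is.null(fits) && !is.null(fits[[as.character(j)]]))
      fits[[as.character(j)]] else
        fitZinb(M[, j], tr, covariates = X, offset = offset, hessian = FALSE)
    if (zf@method == "nb") {
      g0 <- -Inf; g1 <- 0; gX <- numeric(q)
    } else {
      g0 <- zf@gamma[1]; g1 <- zf@gamma[2]
      gX <- if (q) zf@gamma[2 + seq_len(q)] else numeric(0)
    }
    aX <- if (q) zf@alpha[2 + seq_len(q)] else numeric(0)
    tab[k, c("nie", "niep", "niea")] <-
      nieComponents(betaM[k], zf@alpha[1], zf@alpha[2], g0, g1,
                    alphaX = aX, gammaX = gX, x = xProfile)
  }
  new("MediationEffects", nde = unname(beta["treatment"]),
      beta0 = unname(beta["(Intercept)"]), sigma2 = sigma2,
      betaM = betaM, table = tab, xProfile = as.numeric(xProfile),
      nieTotal = totalNie(tab$nie))
}

#' Bootstrap confidence intervals for a taxon's mediation effects
#'
#' Percentile intervals for NIE, NIEP and NIEA from `nRep` nonparametric
#' bootstrap resamples (sample rows with replacement, re-estimate).
#' Resamples whose re-fit fails are dropped; more than 20% failures is an
#' error.
#'
#' @inheritParams estimateEffects
#' @param taxon the taxon whose effects are summarized.
#' @param selected taxon set for the outcome model (defaults to `taxon`).
#' @param nRep number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @return data.frame with rows `nie`, `niep`, `niea` and columns
#'   `effect`, `point`, `lower`, `upper`, `level`, `nRep`.
#' @export
effectCI <- function(Y, treatment, M, taxon, selected = taxon,
                     covariates = NULL, nRep = 1000L, level = 0.95,
                     xProfile = NULL, offset = NULL, fits = NULL) {
  if (nRep < 1) stop("nRep must be at least 1")
  if (!taxon %in% selected) selected <- c(taxon, selected)
  M <- as.matrix(M)
  n <- length(Y)
  point <- estimateEffects(Y, treatment, M, selected, covariates = covariates,
                           xProfile = xProfile, offset = offset, fits = fits)
  k <- match(taxon, point@table$taxon)
  pt <- unlist(point@table[k, c("nie", "niep", "niea")])
  draws <- matrix(NA_real_, nRep, 3)
  fails <- 0L
  for (b in seq_len(nRep)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      estimateEffects(Y[idx], treatment[idx], M[idx, , drop = FALSE],
                      selected,
                      covariates = if (is.null(covariates)) NULL else
                        covariates[idx, , drop = FALSE],
                      xProfile = xProfile,
                      offset = if (is.null(offset)) NULL else offset[idx]),
      error = function(e) NULL)
    if (is.null(est)) { fails <- fails + 1L; next }
    kk <- match(taxon, est@table$taxon)
    draws[b, ] <- unlist(est@table[kk, c("nie", "niep", "niea")])
  }
  if (fails > 0.2 * nRep)
    stop(sprintf("bootstrap re-fit failure rate %.0f%% exceeds 20%%",
                 100 * fails / nRep))
  a <- (1 - level) / 2
  out <- data.frame(effect = c("nie", "niep", "niea"), point = unname(pt),
                    lower = NA_real_, upper = NA_real_,
                    level = level, nRep = as.integer(nRep))
  for (j in 1:3) {
    qs <- quantile(draws[, j], c(a, 1 - a), na.rm = TRUE, names = FALSE)
    out$lower[j] <- qs[1]; out$upper[j] <- qs[2]
  }
  bad <- out$lower > out$point | out$upper < out$point
  if (any(bad))
    stop("degenerate bootstrap distribution: percentile interval excludes ",
         "the point estimate for ", paste(out$effect[bad], collapse = ", "))
  out
}

setMethod("show", "MediationEffects", function(object) {
  cat(sprintf("MediationEffects: NDE = %.4f, total NIE = %.4f (%d taxa)\n",
              object@nde, object@nieTotal, nrow(object@table)))
  print(object@table, row.names = FALSE)
})
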