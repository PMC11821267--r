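#' Draw the per-taxon coefficient scheme
#'
#' Taxa fall into fixed classes. With `N(a, b)` denoting a normal with mean
#' `a` and variance `b`: taxa 1-3 draw `gamma1, alpha1 ~ N(-2, 1)` and
#' `betaM ~ N(2, 1)`; taxon 4 has `gamma1 = 0`; taxon 5 has `alpha1 = 0`;
#' taxa 6-10 have `gamma1 = alpha1 = 0` with `betaM ~ N(2, 1)`; taxa 11-15
#' have both treatment effects but `betaM = 0`; taxa 16-20 only `gamma1`;
#' taxa 21-25 only `alpha1`; taxa 26..m are fully null. Shared draws:
#' `gamma0 ~ U(-2, 2)`, `phi ~ U(0.1, 10)`; fixed scalars `alpha0 = -7`,
#' `beta0 = 1`, `beta1 = -2`, `sigma2 = 1`. Exactly taxa 1-5 are causal
#' mediators (`betaM != 0` and a nonzero treatment path).
#'
#' Uses the current RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param m number of taxa (at least 26, so every class is populated).
#' @return a [CoefficientScheme-class].
#' @export
drawScheme <- function(m) {
  if (m < 26) stop("m must be at least 26: the coefficient classes are ",
                   "undefined for fewer taxa")
  gamma0 <- runif(m, -2, 2)
  phi <- runif(m, 0.1, 10)
  gamma1 <- numeric(m)
  alpha1 <- numeric(m)
  betaM <- numeric(m)
  g1idx <- c(1:3, 5, 11:20)
  a1idx <- c(1:4, 11:15, 21:25)
  gamma1[g1idx] <- rnorm(length(g1idx), -2, 1)
  alpha1[a1idx] <- rnorm(length(a1idx), -2, 1)
  betaM[1:10] <- rnorm(10, 2, 1)
  taxa <- data.frame(gamma0 = gamma0, gamma1 = gamma1, alpha1 = alpha1,
                     betaM = betaM, phi = phi)
  new("CoefficientScheme", taxa = taxa, alpha0 = -7, beta0 = 1,
      beta1 = -2, sigma2 = 1,
      causal = betaM != 0 & (alpha1 != 0 | gamma1 != 0))
}

# shared machinery: draw counts given treatment and log depth
drawCounts <- function(scheme, tr, logS, family = c("zinb", "hurdle_nb",
                                                    "hurdle_poisson")) {
  family <- match.arg(family)
  n <- length(tr)
  m <- nrow(scheme@taxa)
  M <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    co <- scheme@taxa[j, ]
    pi <- plogis(co$gamma0 + co$gamma1 * tr)
    lam <- exp(logS + scheme@alpha0 + co$alpha1 * tr)
    M[, j] <- switch(family,
      zinb = rzinb(n, pi, lam, co$phi),
      hurdle_nb = rhurdleNB(n, pi, lam, co$phi),
      hurdle_poisson = rhurdleNB(n, pi, lam, Inf))
  }
  colnames(M) <- paste0("taxon", seq_len(m))
  M
}

buildSimExperiment <- function(M, tr, Y, logS, scheme, generator, seed,
                               Xu = NULL) {
  cnt <- t(M)
  colnames(cnt) <- paste0("sample", seq_len(ncol(cnt)))
  me <- MediationExperiment(
    cnt, treatment = tr, outcome = Y,
    covariates = NULL, logDepth = logS,
    rowData = S4Vectors::DataFrame(scheme@taxa, causal = scheme@causal),
    metadata = list(generator = generator, seed = seed, scheme = scheme))
  if (!is.null(Xu)) {
    colnames(Xu) <- paste0("u", seq_len(ncol(Xu)))
    for (k in seq_len(ncol(Xu))) colData(me)[[colnames(Xu)[k]]] <- Xu[, k]
    metadata(me)$unobservedConfounders <- colnames(Xu)
  }
  me
}

#' Simulate a ZINB mediation dataset
#'
#' Treatment `T ~ Bernoulli(0.5)`; per-sample log depth
#' `log(S) ~ U(7.1, 10.5)` used as the count-model offset; counts from the
#' ZINB mixture with `logit(pi_ij) = gamma0_j + gamma1_j T_i` and
#' `log(lambda_ij) = log(S_i) + alpha0 + alpha1_j T_i`; outcome
#' `Y ~ N(beta0 + beta1 T + betaM' M, sigma2)`. Ground-truth causal labels
#' are attached to `rowData` (exactly taxa 1-5 under the default scheme).
#' The overall zero fraction of the count matrix is about 50-60%.
#'
#' @param n number of samples (at least 10).
#' @param m number of taxa (at least 26).
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @param scheme optional [CoefficientScheme-class] overriding the default
#'   draw (e.g. with modified coefficients).
#' @return a [MediationExperiment-class] with `logDepth`, truth labels and
#'   the scheme in `metadata`.
#' @examples
#' sim <- simulateZinbData(50, 30, seed = 1)
#' mean(assay(sim, "counts") == 0)
#' @export
simulateZinbData <- function(n, m = 100L, seed = 1L, scheme = NULL) {
  stopifnot(n >= 10)
  set.seed(seed)
  if (is.null(scheme)) scheme <- drawScheme(m)
  stopifnot(nrow(scheme@taxa) == m)
  tr <- rbinom(n, 1L, 0.5)
  logS <- runif(n, 7.1, 10.5)
  M <- drawCounts(scheme, tr, logS, "zinb")
  Y <- scheme@beta0 + scheme@beta1 * tr +
    drop(M %*% scheme@taxa$betaM) + rnorm(n, 0, sqrt(scheme@sigma2))
  buildSimExperiment(M, tr, Y, logS, scheme, "zinb", seed)
}

#' Simulate a hurdle Poisson / hurdle NB mediation dataset
#'
#' Identical to [simulateZinbData()] except the counts follow a hurdle
#' model: zero with probability `pi_ij`, otherwise a zero-truncated NB
#' (or Poisson, the `phi = Inf` limit) draw. Used to probe robustness of
#' the ZINB-based test under count-model misspecification.
#'
#' @inheritParams simulateZinbData
#' @param family `"nb"` or `"poisson"`.
#' @return a [MediationExperiment-class].
#' @export
simulateHurdleData <- function(n, m = 100L, family = c("nb", "poisson"),
                               seed = 1L, scheme = NULL) {
  family <- match.arg(family)
  stopifnot(n >= 10)
  set.seed(seed)
  if (is.null(scheme)) scheme <- drawScheme(m)
  stopifnot(nrow(scheme@taxa) == m)
  tr <- rbinom(n, 1L, 0.5)
  logS <- runif(n, 7.1, 10.5)
  M <- drawCounts(scheme, tr, logS,
                  if (family == "nb") "hurdle_nb" else "hurdle_poisson")
  Y <- scheme@beta0 + scheme@beta1 * tr +
    drop(M %*% scheme@taxa$betaM) + rnorm(n, 0, sqrt(scheme@sigma2))
  buildSimExperiment(M, tr, Y, logS, scheme,
                     paste0("hurdle_", family), seed)
}

#' Simulate a dataset with unmeasured treatment-outcome confounders
#'
#' Violates the no-unmeasured-confounding assumption for the
#' treatment-outcome relationship: `d` latent standard-normal confounders
#' `X_u` drive both the treatment, via
#' `logit(eta_i) = Delta_u' X_iu` with `Delta_u ~ N(0.2 h, 0.5)` (mean /
#' variance), and the outcome, via an added `betaU' X_iu` term with
#' `betaU ~ N(0.2 h, 0.5)`. Larger `h` means stronger confounding.
#' Counts still follow the ZINB model; the nonzero treatment-path and
#' outcome-path coefficients are redrawn from `N(-5, 1)` and `N(5, 1)`
#' respectively (class structure unchanged).
#'
#' The confounders are stored in `colData` (columns `u1..ud`) for
#' inspection but are *not* registered as observed covariates, so the
#' mediation pipeline does not adjust for them.
#'
#' @inheritParams simulateZinbData
#' @param h confounding strength (the study grid is `1, 3, 9`; any
#'   non-negative value is allowed, `h = 0` giving centered confounding).
#' @param d number of latent confounders (default 3).
#' @return a [MediationExperiment-class].
#' @export
simulateConfoundedData <- function(n, m = 100L, h = 1, d = 3L, seed = 1L,
                                   scheme = NULL) {
  stopifnot(n >= 10, h >= 0, d >= 1)
  set.seed(seed)
  if (is.null(scheme)) {
    scheme <- drawScheme(m)
    tx <- scheme@taxa
    tx$gamma1[tx$gamma1 != 0] <- rnorm(sum(tx$gamma1 != 0), -5, 1)
    tx$alpha1[tx$alpha1 != 0] <- rnorm(sum(tx$alpha1 != 0), -5, 1)
    tx$betaM[tx$betaM != 0] <- rnorm(sum(tx$betaM != 0), 5, 1)
    scheme@taxa <- tx
    scheme@causal <- tx$betaM != 0 & (tx$alpha1 != 0 | tx$gamma1 != 0)
  }
  stopifnot(nrow(scheme@taxa) == m)
  Xu <- matrix(rnorm(n * d), n, d)
  deltaU <- rnorm(d, 0.2 * h, sqrt(0.5))
  betaU <- rnorm(d, 0.2 * h, sqrt(0.5))
  tr <- rbinom(n, 1L, plogis(drop(Xu %*% deltaU)))
  logS <- runif(n, 7.1, 10.5)
  M <- drawCounts(scheme, tr, logS, "zinb")
  Y <- scheme@beta0 + scheme@beta1 * tr + drop(M %*% scheme@taxa$betaM) +
    drop(Xu %*% betaU) + rnorm(n, 0, sqrt(scheme@sigma2))
  buildSimExperiment(M, tr, Y, logS, scheme, "confounded", seed, Xu = Xu)
}

setMethod("show", "CoefficientScheme", function(object) {
  cat(sprintf("CoefficientScheme: %d taxa, %d causal; alpha0 = %g, beta0 = %g, beta1 = %g, sigma2 = %g\n",
              nrow(object@taxa), sum(object@causal), object@alpha0,
              object@beta0, object@beta1, object@sigma2))
})

#' @rdname drawScheme
#' @param x a `CoefficientScheme`.
#' @export
setMethod("causalTaxa", "CoefficientScheme", function(x) x@causal)
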