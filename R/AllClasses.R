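#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @import SummarizedExperiment
NULL

#' Container for a microbiome mediation dataset
#'
#' `MediationExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with the conventions this package relies on: a `"counts"` assay holding
#' non-negative integer taxon abundances (taxa as rows, samples as columns),
#' a binary `treatment` column and a numeric `outcome` column in `colData`,
#' plus optional numeric covariate columns and an optional `logDepth` column
#' (per-sample log sequencing depth, used as the count-model offset).
#'
#' @slot covariateNames character vector naming the `colData` columns treated
#'   as observed confounders (may be empty).
#' @export
setClass("MediationExperiment",
  contains = "SummarizedExperiment",
  slots = c(covariateNames = "character")
)

setValidity("MediationExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(cnt < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    if (any(abs(cnt - round(cnt)) > 1e-8, na.rm = TRUE))
      msg <- c(msg, "counts must be integers")
  }
  cd <- colData(object)
  if (!"treatment" %in% colnames(cd))
    msg <- c(msg, "colData column 'treatment' is required")
  else if (!all(cd$treatment %in% c(0, 1)))
    msg <- c(msg, "treatment must be coded 0/1")
  if (!"outcome" %in% colnames(cd))
    msg <- c(msg, "colData column 'outcome' is required")
  else if (!is.numeric(cd$outcome))
    msg <- c(msg, "outcome must be numeric")
  if (length(object@covariateNames) &&
      !all(object@covariateNames %in% colnames(cd)))
    msg <- c(msg, "covariateNames must name colData columns")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  if (length(msg)) msg else TRUE
})

#' Fitted zero-inflated negative binomial regression for one taxon
#'
#' Result of [fitZinb()]. The zero model is
#' \eqn{logit(\pi_i) = \gamma_0 + \gamma_1 T_i + \gamma_x^\top X_i} and the
#' count model \eqn{\log(\lambda_i) = o_i + \alpha_0 + \alpha_1 T_i +
#' \alpha_x^\top X_i} with NB dispersion \eqn{\phi} (variance
#' \eqn{\lambda + \lambda^2/\phi}).
#'
#' @slot gamma named numeric, zero-model coefficients (`NA` for the
#'   NB-only fallback on taxa without zeros).
#' @slot alpha named numeric, count-model coefficients.
#' @slot phi positive scalar, NB dispersion.
#' @slot fittedPi,fittedLambda,fittedMean per-observation fitted structural
#'   zero probability, NB mean, and marginal mean `(1 - pi) * lambda`.
#' @slot covTheta estimated covariance of `(alpha1, gamma1)` (1x1 in the
#'   NB-only fallback), from the inverse observed information.
#' @slot logLik maximized observed-data log-likelihood.
#' @slot converged logical convergence flag, set honestly.
#' @slot method `"zinb"` or `"nb"` (no-zeros fallback).
#' @slot waldDf degrees of freedom for the treatment Wald test (2, or 1 for
#'   the NB-only fallback).
#' @slot nObs number of observations.
#' @slot flags character vector of fitting notes (fallbacks, retries).
#' @export
setClass("ZinbFit", slots = c(
  gamma = "numeric", alpha = "numeric", phi = "numeric",
  fittedPi = "numeric", fittedLambda = "numeric", fittedMean = "numeric",
  covTheta = "matrix", logLik = "numeric", converged = "logical",
  method = "character", waldDf = "integer", nObs = "integer",
  flags = "character"
))

setValidity("ZinbFit", function(object) {
  msg <- character(0)
  n <- object@nObs
  if (length(object@fittedPi) != n || length(object@fittedLambda) != n ||
      length(object@fittedMean) != n)
    msg <- c(msg, "fitted vectors must have length nObs")
  if (!(object@phi > 0) || !is.finite(object@phi))
    msg <- c(msg, "phi must be strictly positive and finite")
  dev <- abs(object@fittedMean - (1 - object@fittedPi) * object@fittedLambda)
  if (length(dev) && max(dev) > 1e-6 * (1 + max(object@fittedMean)))
    msg <- c(msg, "fittedMean must equal (1 - fittedPi) * fittedLambda")
  ct <- object@covTheta
  if (!all(is.na(ct))) {
    if (max(abs(ct - t(ct))) > 1e-8)
      msg <- c(msg, "covTheta must be symmetric")
    if (any(diag(ct) < -1e-12, na.rm = TRUE))
      msg <- c(msg, "covTheta diagonal must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Per-taxon Table 2-style coefficient scheme for the simulators
#'
#' Holds the per-taxon regression coefficients (`gamma0`, `gamma1`, `alpha1`,
#' `betaM`, `phi`), the shared scalars (`alpha0`, `beta0`, `beta1`, `sigma2`),
#' and the causal-mediator labels (`TRUE` iff `betaM != 0` and at least one of
#' `alpha1`, `gamma1` is nonzero).
#'
#' @slot taxa data.frame with one row per taxon and columns `gamma0`,
#'   `gamma1`, `alpha1`, `betaM`, `phi`.
#' @slot alpha0,beta0,beta1,sigma2 shared scalar parameters.
#' @slot causal logical causal-mediator labels.
#' @export
setClass("CoefficientScheme", slots = c(
  taxa = "data.frame", alpha0 = "numeric", beta0 = "numeric",
  beta1 = "numeric", sigma2 = "numeric", causal = "logical"
))

setValidity("CoefficientScheme", function(object) {
  msg <- character(0)
  need <- c("gamma0", "gamma1", "alpha1", "betaM", "phi")
  if (!all(need %in% colnames(object@taxa)))
    msg <- c(msg, sprintf("taxa must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(object@taxa$phi <= 0)) msg <- c(msg, "phi must be positive")
    lab <- object@taxa$betaM != 0 &
      (object@taxa$alpha1 != 0 | object@taxa$gamma1 != 0)
    if (!identical(unname(lab), unname(object@causal)))
      msg <- c(msg, "causal labels must match the null-hypothesis rule")
  }
  if (!(object@sigma2 > 0)) msg <- c(msg, "sigma2 must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-taxon mediation effect estimates
#'
#' Point estimates of the natural direct effect (NDE, the treatment
#' coefficient of the outcome regression) and, for each selected taxon, the
#' natural indirect effect (NIE) with its presence-absence (NIEP) and
#' abundance (NIEA) components.
#'
#' @slot nde natural direct effect (outcome-model treatment coefficient).
#' @slot beta0 outcome-model intercept.
#' @slot sigma2 outcome-model residual variance.
#' @slot betaM named numeric, outcome-model coefficients of selected taxa.
#' @slot table data.frame with columns `taxon`, `nie`, `niep`, `niea`.
#' @slot xProfile covariate profile at which effects are evaluated.
#' @slot nieTotal sum of per-taxon NIE.
#' @export
setClass("MediationEffects", slots = c(
  nde = "numeric", beta0 = "numeric", sigma2 = "numeric",
  betaM = "numeric", table = "data.frame", xProfile = "numeric",
  nieTotal = "numeric"
))

#' Results of a full mediation test run
#'
#' One row of `results` per taxon examined after screening: CRT p-value
#' `p1`, Wald p-value `p2`, joint-significance `pmax = max(p1, p2)`,
#' BH-adjusted `pAdj`, selection flag, effect estimates and optional
#' bootstrap confidence bounds, plus per-taxon flags.
#'
#' @slot results data.frame of per-taxon results.
#' @slot screen list with elements `D` (screened taxon indices),
#'   `lambdaChosen` and `nFolds` (`NULL` lambda when screening is off).
#' @slot config list echoing the run configuration (B, fdr, seed, ...).
#' @slot effects a [MediationEffects-class] object or `NULL`.
#' @slot method `"zinb"` (zero-inflated CRT) or `"gaussian"` (naive
#'   log-normal baseline).
#' @export
setClass("MediationResults", slots = c(
  results = "data.frame", screen = "list", config = "list",
  effects = "ANY", method = "character"
))

setValidity("MediationResults", function(object) {
  msg <- character(0)
  r <- object@results
  need <- c("taxon", "p1", "p2", "pmax", "pAdj", "selected")
  if (nrow(r) && !all(need %in% colnames(r)))
    msg <- c(msg, "results must carry taxon, p1, p2, pmax, pAdj, selected")
  if (nrow(r)) {
    ok <- is.na(r$pmax) | abs(r$pmax - pmax(r$p1, r$p2)) < 1e-12
    if (!all(ok)) msg <- c(msg, "pmax must equal max(p1, p2)")
    ok <- is.na(r$pAdj) | r$pAdj >= r$pmax - 1e-12
    if (!all(ok)) msg <- c(msg, "pAdj must be >= pmax")
  }
  if (length(msg)) msg else TRUE
})

#' Benchmark report for simulated mediator selection
#'
#' Per-replicate confusion counts and metrics from [runBenchmark()],
#' with aggregate means. Replicates where a metric is undefined (empty
#' selection) are excluded from that metric's mean and counted.
#'
#' @slot perReplicate data.frame with one row per replicate.
#' @slot summary named list of aggregate means and undefined counts.
#' @slot fdr FDR threshold used for selection.
#' @slot method,generator character tags of the pipeline and simulator.
#' @slot nReplicates,seed integers.
#' @export
setClass("BenchmarkReport", slots = c(
  perReplicate = "data.frame", summary = "list", fdr = "numeric",
  method = "character", generator = "character",
  nReplicates = "integer", seed = "integer"
))
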