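#' Construct a MediationExperiment
#'
#' @param counts taxa-by-samples matrix of non-negative integer counts.
#'   Row names are taxon identifiers, column names sample identifiers.
#' @param treatment binary (0/1, logical, or two-level factor/character)
#'   vector of length `ncol(counts)`.
#' @param outcome numeric outcome vector of length `ncol(counts)`.
#' @param covariates optional numeric matrix or data.frame of observed
#'   confounders, samples in rows.
#' @param logDepth optional per-sample log sequencing depth, used as the
#'   count-model offset when present.
#' @param rowData optional per-taxon annotation (e.g. `causal` labels).
#' @param metadata optional list of run/provenance metadata.
#' @return a [MediationExperiment-class].
#' @examples
#' cnt <- matrix(rpois(12, 4), nrow = 3,
#'               dimnames = list(paste0("taxon", 1:3), paste0("s", 1:4)))
#' me <- MediationExperiment(cnt, treatment = c(0, 1, 0, 1),
#'                           outcome = rnorm(4))
#' treatment(me)
#' @export
MediationExperiment <- function(counts, treatment, outcome,
                                covariates = NULL, logDepth = NULL,
                                rowData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  treatment <- encodeTreatment(treatment)
  cd <- S4Vectors::DataFrame(treatment = treatment,
                             outcome = as.numeric(outcome),
                             row.names = colnames(counts))
  covNames <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(counts))
      stop("covariates must have one row per sample")
    covNames <- colnames(covariates)
    for (nm in covNames) cd[[nm]] <- as.numeric(covariates[[nm]])
  }
  if (!is.null(logDepth)) cd$logDepth <- as.numeric(logDepth)
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             colData = cd, metadata = metadata)
  if (!is.null(rowData)) rowData(se) <- rowData
  new("MediationExperiment", se, covariateNames = covNames)
}

# map a binary treatment encoding onto 0/1
encodeTreatment <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x) || is.character(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) != 2)
      stop("treatment must have exactly two levels, got: ",
           paste(lev, collapse = ", "))
    return(as.integer(as.character(x) == lev[2]))
  }
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1)))
    stop("numeric treatment must be coded 0/1")
  as.integer(x)
}

#' @rdname MediationExperiment
#' @export
setMethod("treatment", "MediationExperiment",
          function(x) colData(x)$treatment)

#' @rdname MediationExperiment
#' @export
setMethod("outcome", "MediationExperiment",
          function(x) colData(x)$outcome)

#' @rdname MediationExperiment
#' @export
setMethod("covariateMatrix", "MediationExperiment", function(x) {
  if (!length(x@covariateNames)) return(NULL)
  as.matrix(as.data.frame(colData(x)[, x@covariateNames, drop = FALSE]))
})

#' @rdname MediationExperiment
#' @export
setMethod("logDepth", "MediationExperiment", function(x) {
  cd <- colData(x)
  if ("logDepth" %in% colnames(cd)) cd$logDepth else NULL
})

#' @rdname MediationExperiment
#' @export
setMethod("causalTaxa", "MediationExperiment", function(x) {
  rd <- rowData(x)
  if ("causal" %in% colnames(rd)) rd$causal else NULL
})

setMethod("show", "MediationExperiment", function(object) {
  callNextMethod()
  cat(sprintf("treatment: %d / %d treated; covariates: %s\n",
              sum(treatment(object)), ncol(object),
              if (length(object@covariateNames))
                paste(object@covariateNames, collapse = ", ") else "none"))
})
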