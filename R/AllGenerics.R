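#' @rdname MediationExperiment
#' @param object,x a `MediationExperiment`.
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))

#' @rdname MediationExperiment
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname MediationExperiment
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' @rdname MediationExperiment
#' @export
setGeneric("logDepth", function(x) standardGeneric("logDepth"))

#' @rdname MediationExperiment
#' @export
setGeneric("causalTaxa", function(x) standardGeneric("causalTaxa"))

#' Run the zero-inflated mediation test pipeline
#'
#' @param x a [MediationExperiment-class].
#' @param ... arguments passed on to the pipeline; see
#'   [runMediation,MediationExperiment-method].
#' @export
setGeneric("runMediation", function(x, ...) standardGeneric("runMediation"))

#' Run the Gaussian-mediator (naive) baseline pipeline
#'
#' @param x a [MediationExperiment-class].
#' @param ... arguments passed on to the pipeline.
#' @export
setGeneric("runNaiveMediation",
           function(x, ...) standardGeneric("runNaiveMediation"))

#' @rdname MediationResults-class
#' @param x a `MediationResults`.
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname MediationResults-class
#' @export
setGeneric("selectedTaxa", function(x) standardGeneric("selectedTaxa"))
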