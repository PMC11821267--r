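#' @importFrom stats plogis qlogis rbinom rnbinom rnorm runif rpois
#'   pchisq dnbinom dpois pnbinom qnbinom ppois qpois glm binomial poisson
#'   coef lm optim optimHess p.adjust pnorm predict quantile sd var
#'   residuals model.matrix setNames fitted glm.fit lm.fit
#' @importFrom utils read.table write.table packageVersion
NULL

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x < -35
  hi <- x > 35
  mid <- !lo & !hi
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out
}

# derive a 32-bit sub-seed from a master seed and a stream index, so that
# per-taxon / per-replicate work is reproducible and order-invariant
deriveSeed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 16807
  as.integer(s %% 2147483629) + 1L
}

# validate a count vector: non-negative integers
checkCounts <- function(k, what = "k") {
  if (any(k < 0) || any(abs(k - round(k)) > 1e-8))
    stop(what, " must contain non-negative integers")
  invisible(round(k))
}

stopWithClass <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
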