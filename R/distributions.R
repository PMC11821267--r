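#' Zero-inflated negative binomial density and sampler
#'
#' The ZINB mixture places probability `pi` on a structural zero and
#' `1 - pi` on NB(`mu`, `size`) counts, parameterized so that the NB mean is
#' `mu` and the variance `mu + mu^2/size`. `size = Inf` gives the Poisson
#' limit.
#'
#' @param x vector of non-negative integer counts.
#' @param pi structural-zero probability in `[0, 1]`.
#' @param mu positive NB mean.
#' @param size positive NB dispersion (`phi`); `Inf` for Poisson.
#' @param log logical; return log density?
#' @return `dzinb` the (log) probability mass; `rzinb` an integer vector of
#'   `n` draws.
#' @examples
#' dzinb(0:5, pi = 0.3, mu = 4, size = 1.5)
#' sum(dzinb(0:500, pi = 0.3, mu = 4, size = 1.5)) # ~1
#' @export
dzinb <- function(x, pi, mu, size, log = FALSE) {
  checkCounts(x, "x")
  stopifnot(all(pi >= 0 & pi <= 1), all(mu > 0), all(size > 0))
  n <- max(length(x), length(pi), length(mu), length(size))
  x <- rep_len(x, n); pi <- rep_len(pi, n)
  mu <- rep_len(mu, n); size <- rep_len(size, n)
  lnb <- nbLogPmf(x, mu, size)
  out <- ifelse(pi >= 1, ifelse(x == 0, 0, -Inf),
                log1p(-pi) + lnb)
  z <- x == 0 & pi < 1
  if (any(z)) {
    # log(pi + (1 - pi) * NB(0)) via log-sum-exp
    a <- log(pi[z])
    b <- log1p(-pi[z]) + lnb[z]
    m <- pmax(a, b)
    m[!is.finite(m)] <- 0
    out[z] <- m + log(exp(a - m) + exp(b - m))
  }
  if (log) out else exp(out)
}

# NB log pmf with mean/dispersion parameterization, Poisson limit at size=Inf
nbLogPmf <- function(x, mu, size) {
  out <- numeric(length(x))
  po <- !is.finite(size)
  if (any(po)) out[po] <- dpois(x[po], mu[po], log = TRUE)
  if (any(!po)) out[!po] <- dnbinom(x[!po], size = size[!po],
                                    mu = mu[!po], log = TRUE)
  out
}

#' @rdname dzinb
#' @param n number of draws.
#' @export
rzinb <- function(n, pi, mu, size) {
  pi <- rep_len(pi, n); mu <- rep_len(mu, n); size <- rep_len(size, n)
  z <- rbinom(n, 1L, pi)
  po <- !is.finite(size)
  y <- integer(n)
  if (any(po)) y[po] <- rpois(sum(po), mu[po])
  if (any(!po)) y[!po] <- rnbinom(sum(!po), size = size[!po], mu = mu[!po])
  y[z == 1L] <- 0L
  y
}

#' Hurdle negative binomial density and sampler
#'
#' Two-part count model: `P(X = 0) = pi` and positive counts follow
#' NB(`mu`, `size`) truncated at zero, scaled by `1 - pi`. `size = Inf`
#' gives the hurdle Poisson model.
#'
#' @inheritParams dzinb
#' @return `dhurdleNB` the (log) probability mass; `rhurdleNB` an integer
#'   vector of `n` draws.
#' @examples
#' sum(dhurdleNB(0:500, pi = 0.3, mu = 5, size = 2)) # ~1
#' @export
dhurdleNB <- function(x, pi, mu, size, log = FALSE) {
  checkCounts(x, "x")
  stopifnot(all(pi >= 0 & pi <= 1), all(mu > 0), all(size > 0))
  n <- max(length(x), length(pi), length(mu), length(size))
  x <- rep_len(x, n); pi <- rep_len(pi, n)
  mu <- rep_len(mu, n); size <- rep_len(size, n)
  lnb0 <- nbLogPmf(rep(0L, n), mu, size)
  out <- ifelse(x == 0, log(pi),
                log1p(-pi) + nbLogPmf(x, mu, size) - log1p(-exp(lnb0)))
  if (log) out else exp(out)
}

#' @rdname dhurdleNB
#' @export
rhurdleNB <- function(n, pi, mu, size) {
  pi <- rep_len(pi, n); mu <- rep_len(mu, n); size <- rep_len(size, n)
  z <- rbinom(n, 1L, pi)
  y <- integer(n)
  pos <- z == 0L
  if (any(pos)) {
    po <- !is.finite(size) & pos
    nb <- is.finite(size) & pos
    if (any(po)) {
      p0 <- ppois(0L, mu[po])
      y[po] <- qpois(runif(sum(po), p0, 1), mu[po])
    }
    if (any(nb)) {
      p0 <- pnbinom(0L, size = size[nb], mu = mu[nb])
      y[nb] <- qnbinom(runif(sum(nb), p0, 1), size = size[nb], mu = mu[nb])
    }
    y[pos] <- pmax(y[pos], 1L)
  }
  y
}
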