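# Independent brute-force oracles, coded directly from the probability
# definitions (gamma functions, explicit mixtures), deliberately not sharing
# code with the package implementation.

oracleZinbLogPmf <- function(k, pi, lam, phi) {
  nb <- exp(lgamma(k + phi) - lgamma(phi) - lgamma(k + 1)) *
    (phi / (phi + lam))^phi * (lam / (phi + lam))^k
  log(pi * (k == 0) + (1 - pi) * nb)
}

oracleHurdleLogPmf <- function(k, pi, lam, phi) {
  nb <- function(x) exp(lgamma(x + phi) - lgamma(phi) - lgamma(x + 1)) *
    (phi / (phi + lam))^phi * (lam / (phi + lam))^x
  if (k == 0) log(pi) else log((1 - pi) * nb(k) / (1 - nb(0)))
}

oracleCrtStat <- function(y, yhat, m, mhat) {
  num <- 0
  for (i in seq_along(y)) num <- num + (y[i] - yhat[i]) * (m[i] - mhat[i])
  den <- 0
  for (i in seq_along(m)) den <- den + (m[i] - mhat[i])^2
  abs(num) / sqrt(den)
}

# textbook BH step-up: adj_(i) = min_{i' >= i} p_(i') * n / i', capped at 1
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (r in seq_len(n)) {
    cand <- vapply(r:n, function(rr) p[o[rr]] * n / rr, 0)
    adj[o[r]] <- min(1, min(cand))
  }
  adj
}

oracleConfusion <- function(selected, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(selected)) {
    if (selected[i] && truth[i]) tp <- tp + 1L
    else if (selected[i] && !truth[i]) fp <- fp + 1L
    else if (!selected[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# one simulated taxon in the style of the study generator
makeTaxon <- function(n, gamma0, gamma1, alpha0, alpha1, phi, seed) {
  set.seed(seed)
  tr <- rbinom(n, 1, 0.5)
  logS <- runif(n, 7.1, 10.5)
  y <- rzinb(n, plogis(gamma0 + gamma1 * tr),
             exp(logS + alpha0 + alpha1 * tr), phi)
  list(y = y, tr = tr, logS = logS)
}

# manually assembled ZinbFit with constant fitted values (for samplers/tests)
makeFit <- function(n, pi, lam, phi) {
  new("ZinbFit",
      gamma = c(`(Intercept)` = qlogis(min(max(pi, 1e-12), 1 - 1e-12)),
                treatment = 0),
      alpha = c(`(Intercept)` = log(lam), treatment = 0),
      phi = phi,
      fittedPi = rep(pi, n), fittedLambda = rep(lam, n),
      fittedMean = rep((1 - pi) * lam, n),
      covTheta = diag(2), logLik = 0, converged = TRUE, method = "zinb",
      waldDf = 2L, nObs = as.integer(n), flags = character(0))
}
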