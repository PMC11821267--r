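test_that("indirect-effect decomposition obeys its null branches and identity", {
  # betaM = 0: no mediator-outcome path
  expect_equal(unname(nieComponents(0, -1, -2, 0.5, -1)), c(0, 0, 0))
  # alpha1 = gamma1 = 0: no treatment-mediator path
  expect_equal(unname(nieComponents(2, -1, 0, 0.5, 0)), c(0, 0, 0))
  # gamma1 = 0: presence path inactive, nie collapses onto niea
  v <- nieComponents(2, -1, -2, 0.5, 0)
  expect_equal(unname(v[["niep"]]), 0)
  expect_equal(v[["nie"]], v[["niea"]])
  # alpha1 = 0: abundance path inactive, nie collapses onto niep
  v <- nieComponents(2, -1, 0, 0.5, -2)
  expect_equal(unname(v[["niea"]]), 0)
  expect_equal(v[["nie"]], v[["niep"]])
  # exact additivity and antisymmetry over random draws
  set.seed(42)
  for (r in 1:500) {
    b <- rnorm(1, 0, 3); a0 <- rnorm(1); a1 <- rnorm(1, 0, 2)
    g0 <- rnorm(1); g1 <- rnorm(1, 0, 2)
    v <- nieComponents(b, a0, a1, g0, g1)
    expect_lt(abs(v[["nie"]] - (v[["niep"]] + v[["niea"]])), 1e-10)
    # swapping the with/without-treatment roles flips the sign of nie
    w <- nieComponents(b, a0 + a1, -a1, g0 + g1, -g1)
    expect_equal(w[["nie"]], -v[["nie"]], tolerance = 1e-10)
  }
  # overflow-safe for extreme linear predictors
  v <- nieComponents(1, 200, 100, 400, 100)
  expect_true(all(is.finite(v)))
})

test_that("effects honour covariate profiles and sum to the total NIE", {
  expect_equal(totalNie(numeric(0)), 0)
  expect_equal(totalNie(c(0.5, -0.2)), 0.3)
  # two-route check: per-taxon components vs direct evaluation of the
  # difference-of-means display, with covariates
  set.seed(9)
  for (r in 1:50) {
    b <- rnorm(1); a0 <- rnorm(1); a1 <- rnorm(1); g0 <- rnorm(1)
    g1 <- rnorm(1); aX <- rnorm(2); gX <- rnorm(2); x <- rnorm(2)
    v <- nieComponents(b, a0, a1, g0, g1, alphaX = aX, gammaX = gX, x = x)
    direct <- b * (exp(a0 + a1 + sum(aX * x)) /
                     (1 + exp(g0 + g1 + sum(gX * x))) -
                   exp(a0 + sum(aX * x)) / (1 + exp(g0 + sum(gX * x))))
    expect_equal(unname(v[["nie"]]), direct, tolerance = 1e-10)
  }
})

test_that("estimateEffects recovers generating effects without bias", {
  # mean estimate over replicates within 3 Monte-Carlo SEs of the truth
  truth <- list(g0 = 0.2, g1 = -1.5, a0 = 1.2, a1 = -1, phi = 3, betaM = 2)
  trueNie <- nieComponents(truth$betaM, truth$a0, truth$a1,
                           truth$g0, truth$g1)
  R <- 30
  est <- matrix(NA_real_, R, 3)
  for (r in 1:R) {
    set.seed(300 + r)
    n <- 500
    tr <- rbinom(n, 1, 0.5)
    mj <- rzinb(n, plogis(truth$g0 + truth$g1 * tr),
                exp(truth$a0 + truth$a1 * tr), truth$phi)
    Y <- 1 - 2 * tr + truth$betaM * mj + rnorm(n)
    e <- estimateEffects(Y, tr, matrix(mj, ncol = 1), selected = 1)
    est[r, ] <- unlist(e@table[1, c("nie", "niep", "niea")])
  }
  for (k in 1:3) {
    mcse <- sd(est[, k]) / sqrt(R)
    expect_lt(abs(mean(est[, k]) - trueNie[k]), 3 * mcse + 1e-8)
  }
})

test_that("null-taxon effect estimates shrink with sample size", {
  absEst <- function(n) {
    vals <- numeric(12)
    for (r in seq_along(vals)) {
      set.seed(4000 + r)
      tr <- rbinom(n, 1, 0.5)
      mj <- rzinb(n, plogis(0.5 - 1.5 * tr), exp(1 - tr), 2)
      Y <- 1 - 2 * tr + rnorm(n)  # betaM = 0 in truth
      e <- estimateEffects(Y, tr, matrix(mj, ncol = 1), selected = 1)
      vals[r] <- abs(e@table$nie[1])
    }
    mean(vals)
  }
  expect_lt(absEst(800), absEst(100))
})

test_that("degenerate designs for effect estimation are rejected", {
  set.seed(2)
  M <- matrix(rpois(60, 3), 20, 3)
  Y <- rnorm(20)
  expect_error(estimateEffects(Y, rep(1, 20), M, selected = 1),
               "constant")
  # duplicated mediator column -> collinear design named in the error
  M2 <- cbind(M, M[, 1])
  expect_error(
    estimateEffects(Y, rep(0:1, 10), M2, selected = c(1, 4)),
    "rank deficient")
  expect_error(estimateEffects(Y, rep(0:1, 10), M, selected = integer(0)),
               "empty")
})

test_that("bootstrap intervals are ordered, reproducible and informative", {
  set.seed(8)
  n <- 150
  tr <- rbinom(n, 1, 0.5)
  mj <- rzinb(n, plogis(0.3 - 1.5 * tr), exp(1.5 - tr), 3)
  Y <- 1 - 2 * tr + 1.5 * mj + rnorm(n)
  M <- matrix(mj, ncol = 1)
  expect_error(effectCI(Y, tr, M, taxon = 1, nRep = 0), "at least 1")
  set.seed(77)
  ci1 <- effectCI(Y, tr, M, taxon = 1, nRep = 120)
  set.seed(77)
  ci2 <- effectCI(Y, tr, M, taxon = 1, nRep = 120)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower <= ci1$point & ci1$point <= ci1$upper))
  expect_equal(ci1$point[1], ci1$point[2] + ci1$point[3], tolerance = 1e-10)
})

test_that("interval width shrinks as the sample grows", {
  width <- function(n) {
    ws <- numeric(8)
    for (r in seq_along(ws)) {
      set.seed(600 + r)
      tr <- rbinom(n, 1, 0.5)
      mj <- rzinb(n, plogis(0.3 - 1.2 * tr), exp(1.5 - tr), 3)
      Y <- 1 - 2 * tr + 1.5 * mj + rnorm(n)
      set.seed(700 + r)
      ci <- effectCI(Y, tr, matrix(mj, ncol = 1), taxon = 1, nRep = 60)
      ws[r] <- ci$upper[1] - ci$lower[1]
    }
    median(ws)
  }
  expect_lt(width(400), width(100))
})

test_that("nominal-level intervals cover a null effect at about the right rate", {
  R <- 20
  cover <- logical(R)
  for (r in 1:R) {
    set.seed(900 + r)
    n <- 150
    tr <- rbinom(n, 1, 0.5)
    mj <- rzinb(n, plogis(0.3 - 1.2 * tr), exp(1.5 - tr), 3)
    Y <- 1 - 2 * tr + rnorm(n)  # true NIE = 0
    set.seed(950 + r)
    ci <- effectCI(Y, tr, matrix(mj, ncol = 1), taxon = 1, nRep = 100)
    cover[r] <- ci$lower[1] <= 0 && 0 <= ci$upper[1]
  }
  # 0.95 nominal; 3 binomial SEs at R = 20 reaches down to ~0.80
  expect_gte(mean(cover), 0.80)
})
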