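makeNoiseExperiment <- function(seed, n = 80, m = 30) {
  set.seed(seed)
  tr <- rbinom(n, 1, 0.5)
  M <- matrix(rnbinom(n * m, size = 1, mu = 6), n, m)
  Y <- rnorm(n)
  MediationExperiment(t(M), treatment = tr, outcome = Y)
}

test_that("the pipeline is deterministic and monotone in the FDR threshold", {
  sim <- simulateZinbData(70, 30, seed = 12)
  r1 <- runMediation(sim, B = 20, seed = 5)
  r2 <- runMediation(sim, B = 20, seed = 5)
  expect_identical(resultsTable(r1), resultsTable(r2))
  expect_s4_class(r1, "MediationResults")
  # selection at a stricter threshold is nested in the looser one
  strict <- runMediation(sim, B = 20, seed = 5, fdr = 0.01)
  loose <- runMediation(sim, B = 20, seed = 5, fdr = 0.05)
  expect_true(all(selectedTaxa(strict) %in% selectedTaxa(loose)))
  # p1 values live on the randomization grid
  p1 <- resultsTable(r1)$p1
  p1 <- p1[!is.na(p1)]
  expect_true(all(abs(21 * p1 - round(21 * p1)) < 1e-9))
  expect_true(all(p1 >= 1 / 21))
})

test_that("an empty screened set terminates with zero discoveries", {
  me <- makeNoiseExperiment(2)
  res <- runMediation(me, B = 10, seed = 1002)
  expect_identical(nrow(resultsTable(res)), 0L)
  expect_length(selectedTaxa(res), 0)
  expect_identical(selectionVector(res, 30), rep(FALSE, 30))
})

test_that("one degenerate taxon never aborts the run", {
  set.seed(13)
  n <- 60
  tr <- rbinom(n, 1, 0.5)
  M <- cbind(matrix(rnbinom(n * 4, size = 2, mu = 6), n, 4),
             rep(0L, n))  # all-zero taxon
  Y <- 0.5 * M[, 1] + rnorm(n)
  me <- MediationExperiment(t(M), treatment = tr, outcome = Y)
  res <- runMediation(me, B = 10, seed = 3, screen = FALSE)
  tab <- resultsTable(res)
  expect_identical(nrow(tab), 5L)
  expect_match(tab$flags[tab$index == 5], "untestable")
  expect_true(is.na(tab$pmax[tab$index == 5]))
  # the remaining taxa are still examined (testable ones get p-values)
  expect_gte(sum(!is.na(tab$pmax[tab$index != 5])), 3)
})

test_that("results are invariant to taxon execution order", {
  # each taxon owns an RNG stream keyed by (seed, index), so its p-values do
  # not depend on which other taxa happen to be tested alongside it
  sim <- simulateZinbData(70, 30, seed = 21)
  all30 <- resultsTable(runMediation(sim, B = 15, seed = 9, screen = FALSE))
  screened <- resultsTable(runMediation(sim, B = 15, seed = 9,
                                        screen = TRUE))
  common <- intersect(screened$index, all30$index)
  expect_gt(length(common), 0)
  expect_equal(screened$p1[match(common, screened$index)],
               all30$p1[match(common, all30$index)])
  expect_equal(screened$p2[match(common, screened$index)],
               all30$p2[match(common, all30$index)])
})

test_that("the Gaussian baseline is calibrated on normal-theory mediators", {
  # mediators whose log1p transform is close to Gaussian, null outcome path
  R <- 40
  p1 <- p2 <- numeric(R)
  for (r in 1:R) {
    set.seed(1300 + r)
    n <- 100
    tr <- rbinom(n, 1, 0.5)
    mj <- as.integer(round(exp(rnorm(n, 3, 0.4))))  # treatment-independent
    Y <- 1 - 2 * tr + rnorm(n)
    me <- MediationExperiment(t(matrix(mj, ncol = 1)), treatment = tr,
                              outcome = Y)
    res <- runNaiveMediation(me, B = 24, seed = 1300 + r, screen = FALSE)
    p1[r] <- resultsTable(res)$p1[1]
    p2[r] <- resultsTable(res)$p2[1]
  }
  # discrete-uniform p1 and uniform p2 under the double null
  expect_gt(mean(p1), 0.35); expect_lt(mean(p1), 0.65)
  expect_gt(mean(p2), 0.35); expect_lt(mean(p2), 0.65)
  expect_lt(mean(p2 < 0.05), 0.2)
})

test_that("the naive pipeline is reproducible and reports no decomposition", {
  sim <- simulateZinbData(70, 30, seed = 31)
  a <- runNaiveMediation(sim, B = 15, seed = 2)
  b <- runNaiveMediation(sim, B = 15, seed = 2)
  expect_identical(resultsTable(a), resultsTable(b))
  expect_identical(a@method, "gaussian")
  expect_true(all(is.na(resultsTable(a)$nie)))
})

test_that("joint significance is conservative under the complete null", {
  # both paths off: pmax should stochastically dominate Uniform(0,1)
  R <- 100
  pm <- numeric(R)
  for (r in 1:R) {
    set.seed(5000 + r)
    n <- 120
    tr <- rbinom(n, 1, 0.5)
    mj <- rzinb(n, plogis(0.3), exp(1.5), 2)      # alpha1 = gamma1 = 0
    Y <- 1 - 2 * tr + rnorm(n)                     # betaM = 0
    yhat <- distillOutcome(Y, tr, matrix(mj, ncol = 1), j = 1)
    fit <- fitZinb(mj, tr)
    p1 <- zidcrtPvalue(Y, yhat, mj, fit, tr, B = 30)$p1
    p2 <- tryCatch(waldTest(fit)$p, error = function(e) NA)
    pm[r] <- max(p1, p2)
  }
  pm <- pm[!is.na(pm)]
  for (t in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(pm <= t), t + 3 * sqrt(t * (1 - t) / length(pm)))
})

test_that("selected taxa carry effect estimates and honest bookkeeping", {
  sim <- simulateZinbData(150, 30, seed = 44)
  res <- runMediation(sim, B = 60, seed = 7)
  tab <- resultsTable(res)
  expect_true(all(tab$pAdj >= tab$pmax - 1e-12, na.rm = TRUE))
  expect_equal(tab$pmax, pmax(tab$p1, tab$p2))
  if (any(tab$selected)) {
    sel <- tab[tab$selected, ]
    expect_false(any(is.na(sel$nie)))
    expect_equal(sel$nie, sel$niep + sel$niea, tolerance = 1e-10)
    expect_s4_class(res@effects, "MediationEffects")
  }
})
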