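test_that("the coefficient scheme reproduces the published class table", {
  set.seed(1)
  sc <- drawScheme(60)
  tx <- sc@taxa
  expect_identical(sc@alpha0, -7)
  expect_identical(sc@beta0, 1)
  expect_identical(sc@beta1, -2)
  expect_identical(sc@sigma2, 1)
  # class-wise zero patterns
  expect_true(all(tx$gamma1[1:3] != 0) && all(tx$alpha1[1:3] != 0))
  expect_identical(tx$gamma1[4], 0)
  expect_true(tx$alpha1[4] != 0)
  expect_identical(tx$alpha1[5], 0)
  expect_true(tx$gamma1[5] != 0)
  expect_true(all(tx$gamma1[6:10] == 0) && all(tx$alpha1[6:10] == 0))
  expect_true(all(tx$betaM[1:10] != 0))
  expect_true(all(tx$betaM[11:60] == 0))
  expect_true(all(tx$gamma1[11:15] != 0) && all(tx$alpha1[11:15] != 0))
  expect_true(all(tx$gamma1[16:20] != 0) && all(tx$alpha1[16:20] == 0))
  expect_true(all(tx$gamma1[21:25] == 0) && all(tx$alpha1[21:25] != 0))
  expect_true(all(tx$gamma1[26:60] == 0) && all(tx$alpha1[26:60] == 0))
  # nuisance ranges
  expect_true(all(tx$gamma0 >= -2 & tx$gamma0 <= 2))
  expect_true(all(tx$phi >= 0.1 & tx$phi <= 10))
  # causal labels follow the null-hypothesis rule: exactly taxa 1-5
  expect_identical(which(causalTaxa(sc)), 1:5)
  expect_error(drawScheme(25), "at least 26")
})

test_that("scheme draws have the stated distributions", {
  set.seed(2)
  g1 <- replicate(300, drawScheme(26)@taxa$gamma1[1:3])
  expect_lt(abs(mean(g1) - (-2)), 3 / sqrt(length(g1)))
  expect_lt(abs(sd(g1) - 1), 0.1)
})

test_that("the ZINB generator is reproducible and structurally correct", {
  a <- simulateZinbData(60, 30, seed = 9)
  b <- simulateZinbData(60, 30, seed = 9)
  expect_identical(assay(a, "counts"), assay(b, "counts"))
  expect_identical(outcome(a), outcome(b))
  expect_s4_class(a, "MediationExperiment")
  expect_identical(dim(a), c(30L, 60L))
  expect_identical(which(causalTaxa(a)), 1:5)
  expect_true(all(logDepth(a) >= 7.1 & logDepth(a) <= 10.5))
  expect_true(all(treatment(a) %in% 0:1))
  zf <- mean(assay(a, "counts") == 0)
  expect_gt(zf, 0.35); expect_lt(zf, 0.75)
})

test_that("all four published size settings generate cleanly", {
  for (nm in list(c(100, 100), c(200, 100), c(100, 1000), c(200, 1000))) {
    sim <- simulateZinbData(nm[1], nm[2], seed = 1)
    expect_identical(dim(sim), c(as.integer(nm[2]), as.integer(nm[1])))
    expect_identical(sum(causalTaxa(sim)), 5L)
  }
})

test_that("per-taxon zero fractions match the closed-form zero probability", {
  sim <- simulateZinbData(4000, 26, seed = 15)
  sc <- metadata(sim)$scheme
  tr <- treatment(sim); logS <- logDepth(sim)
  for (j in c(1, 6, 26)) {
    co <- sc@taxa[j, ]
    pi <- plogis(co$gamma0 + co$gamma1 * tr)
    lam <- exp(logS + sc@alpha0 + co$alpha1 * tr)
    p0 <- mean(pi + (1 - pi) * (co$phi / (co$phi + lam))^co$phi)
    emp <- mean(assay(sim, "counts")[j, ] == 0)
    expect_lt(abs(emp - p0), 4 * sqrt(p0 * (1 - p0) / 4000))
  }
})

test_that("removing the mediator paths exposes the direct effect", {
  set.seed(3)
  sc <- drawScheme(26)
  sc@taxa$betaM[] <- 0
  sc@causal <- rep(FALSE, 26)
  sim <- simulateZinbData(2000, 26, seed = 4, scheme = sc)
  fit <- lm(outcome(sim) ~ treatment(sim))
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - (-2)), 3 * est["Std. Error"])
})

test_that("hurdle densities match the printed two-part formula", {
  expect_equal(dhurdleNB(2, pi = 0.3, mu = 5, size = 2, log = TRUE),
               oracleHurdleLogPmf(2, 0.3, 5, 2), tolerance = 1e-12)
  for (k in 0:6)
    expect_equal(dhurdleNB(k, pi = 0.25, mu = 3, size = 1.2, log = TRUE),
                 oracleHurdleLogPmf(k, 0.25, 3, 1.2), tolerance = 1e-12)
  # no hurdle mass: zero count is impossible
  expect_identical(dhurdleNB(0, pi = 0, mu = 3, size = 2, log = TRUE), -Inf)
  # infinite dispersion reduces to the hurdle Poisson model
  k <- 0:60
  expect_equal(dhurdleNB(k, 0.3, 5, 1e9), dhurdleNB(k, 0.3, 5, Inf),
               tolerance = 1e-5)
  expect_equal(dhurdleNB(3, 0.3, 5, Inf, log = TRUE),
               log(0.7) + dpois(3, 5, log = TRUE) - log(1 - dpois(0, 5)))
})

test_that("the hurdle generator respects truncation and reproducibility", {
  a <- simulateHurdleData(50, 26, family = "nb", seed = 6)
  b <- simulateHurdleData(50, 26, family = "nb", seed = 6)
  expect_identical(assay(a, "counts"), assay(b, "counts"))
  expect_identical(metadata(a)$generator, "hurdle_nb")
  # pi = 0 override: no zero mass at all
  set.seed(7)
  sc <- drawScheme(26)
  sc@taxa$gamma0[] <- -Inf
  sim <- simulateHurdleData(40, 26, family = "poisson", seed = 8,
                            scheme = sc)
  expect_true(all(assay(sim, "counts") >= 1))
})

test_that("the confounded generator wires the latent confounders correctly", {
  sim <- simulateConfoundedData(600, 26, h = 3, seed = 10)
  cd <- colData(sim)
  Xu <- cbind(cd$u1, cd$u2, cd$u3)
  expect_identical(ncol(Xu), 3L)
  expect_lt(abs(mean(Xu)), 3 / sqrt(length(Xu)))
  expect_lt(abs(sd(Xu) - 1), 0.1)
  # confounders are kept out of the observed-covariate set
  expect_null(covariateMatrix(sim))
  # coefficient overrides keep the class structure at the stronger scale
  sc <- metadata(sim)$scheme
  expect_identical(which(causalTaxa(sim)), 1:5)
  expect_lt(mean(sc@taxa$gamma1[sc@taxa$gamma1 != 0]), -3)
  expect_gt(mean(sc@taxa$betaM[sc@taxa$betaM != 0]), 3)
  # centered confounding leaves the treatment balanced on average
  trMeans <- vapply(1:10, function(r)
    mean(treatment(simulateConfoundedData(200, 26, h = 0, seed = 100 + r))),
    0)
  expect_lt(abs(mean(trMeans) - 0.5), 3 * sd(trMeans) / sqrt(10) + 0.02)
})
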