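smallControl <- function(seed = 42, nSavedTotal = 600)
  mcmcControl(nChains = 2, nBurnin = 100, nAdapt = 100, thin = 1,
              nSavedTotal = nSavedTotal, seed = seed)

test_that("identical seed and config give bit-identical draws", {
  d <- tinyData(n = 40, p = 3, seed = 21)
  for (m in c("I", "IV")) {
    pr <- priorSpec(m, t = 0.5)
    f1 <- fitBayesOrdinal(d, pr, smallControl())
    f2 <- fitBayesOrdinal(d, pr, smallControl())
    expect_identical(f1@alpha, f2@alpha)
    expect_identical(f1@beta, f2@beta)
    if (m == "IV") expect_identical(f1@gamma, f2@gamma)
    f3 <- fitBayesOrdinal(d, pr, smallControl(seed = 43))
    expect_false(identical(f1@beta, f3@beta))
  }
})

test_that("chains share the posterior but differ by initial state", {
  d <- tinyData(n = 40, p = 2, seed = 22)
  f <- fitBayesOrdinal(d, priorSpec("I"), smallControl())
  expect_false(identical(f@beta[1, , ], f@beta[2, , ]))
})

test_that("every stored threshold draw is strictly increasing", {
  d <- tinyData(n = 50, p = 3, seed = 23)
  for (m in c("I", "II", "III", "IV")) {
    f <- fitBayesOrdinal(d, priorSpec(m, t = 0.3), smallControl())
    expect_true(all(f@alpha[, , 2] > f@alpha[, , 1]))
  }
})

test_that("fit refuses responses with missing categories", {
  X <- standardizeFeatures(matrix(rnorm(40), 20, 2))
  d <- ordinalDataset(X, rep(1:2, 10))
  d@K <- 3L  # sneak in a claimed third level
  expect_error(fitBayesOrdinal(d, priorSpec("I"), smallControl()),
               "category")
})

test_that("intercept-only posterior tracks empirical cumulative frequencies", {
  # p = 0: cumulative probabilities at the thresholds should sit near the
  # empirical frequencies (1/3, 5/6), with a slight pull from the alpha prior
  y <- rep(1:3, c(100, 150, 50))
  d <- ordinalDataset(matrix(numeric(0), 300, 0), y)
  f <- fitBayesOrdinal(d, priorSpec("I"),
                       mcmcControl(nChains = 2, nBurnin = 200, nAdapt = 200,
                                   thin = 1, nSavedTotal = 4000, seed = 9))
  for (k in 1:2) {
    cp <- plogis(f@alpha[, , k])
    target <- c(1 / 3, 5 / 6)[k]
    mcse <- sd(cp) / sqrt(sum(apply(cp, 1, coda::effectiveSize)))
    expect_lt(abs(mean(cp) - target), 3 * mcse + 0.01)
  }
})

test_that("gamma never enters the Model II/III likelihood but gates Model IV", {
  d <- tinyData(n = 30, p = 3, seed = 24)
  st <- parameterState(c(-1, 1), c(0.5, -0.2, 0.1), gamma = c(1, 0, 1))
  stFlip <- parameterState(c(-1, 1), c(0.5, -0.2, 0.1), gamma = c(0, 1, 0))
  for (m in c("II", "III"))
    expect_equal(logLikelihood(st, d, m), logLikelihood(stFlip, d, m))
  expect_false(isTRUE(all.equal(logLikelihood(st, d, "IV"),
                                logLikelihood(stFlip, d, "IV"))))
})

test_that("spike-and-slab LASSO collapses to the Bayesian LASSO when the
           slab rate is pinned at the spike rate", {
  # Gamma(a, b) with a/b = 20 and tiny variance pins lambda ~= lambda0 = 20,
  # making the Model III mixture two identical DE(20) components
  d <- tinyData(n = 60, p = 3, seed = 25)
  ctl <- mcmcControl(nChains = 2, nBurnin = 300, nAdapt = 200, thin = 1,
                     nSavedTotal = 8000, seed = 77)
  fI <- fitBayesOrdinal(d, priorSpec("I", a = 4e4, b = 2e3), ctl)
  fIII <- fitBayesOrdinal(d, priorSpec("III", a = 4e4, b = 2e3,
                                       lambda0 = 20, t = 0.5), ctl)
  for (j in 1:3) {
    bI <- fI@beta[, , j]; bIII <- fIII@beta[, , j]
    mcse <- sqrt(sd(bI)^2 / sum(apply(bI, 1, coda::effectiveSize)) +
                 sd(bIII)^2 / sum(apply(bIII, 1, coda::effectiveSize)))
    expect_lt(abs(mean(bI) - mean(bIII)), 4 * mcse + 0.01)
  }
})

test_that("intercept-only fit works for every variant and p = 0 draws keep shape", {
  y <- rep(1:3, c(10, 15, 8))
  d <- ordinalDataset(matrix(numeric(0), 33, 0), y)
  f <- fitBayesOrdinal(d, priorSpec("IV", t = 0.5), smallControl())
  expect_identical(dim(f@beta)[3L], 0L)
  expect_identical(dim(f@alpha)[3L], 2L)
})
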