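test_that("cumulative probability matches the logistic CDF and its symmetry", {
  expect_identical(cumulativeProb(0, 0), 0.5)
  for (eta in c(-3, 0, 2.5)) expect_equal(cumulativeProb(eta, eta), 0.5)
  # direct evaluation of exp(1)/(1 + exp(1)) as oracle
  expect_equal(cumulativeProb(1, 0), exp(1) / (1 + exp(1)), tolerance = 1e-12)
  # logistic symmetry: F(a - e) + F(-(a - e)) = 1
  set.seed(1)
  a <- rnorm(200, 0, 5); e <- rnorm(200, 0, 5)
  expect_equal(cumulativeProb(a, e) + cumulativeProb(-a, -e), rep(1, 200),
               tolerance = 1e-12)
  # monotone in alpha, antitone in eta
  expect_true(cumulativeProb(1, 0) > cumulativeProb(0.5, 0))
  expect_true(cumulativeProb(1, 1) > cumulativeProb(1, 2))
  # stable far in the tails
  expect_gt(cumulativeProb(40, 0), 1 - 1e-12)
  expect_gt(cumulativeProb(-40, 0), 0)
  expect_error(cumulativeProb(Inf, 0), "finite")
  expect_error(cumulativeProb(0, NaN), "finite")
})

test_that("category probabilities are the first differences of the CDF", {
  # logistic CDF differences as oracle
  expect_equal(categoryProbs(c(-1, 1), 0),
               c(plogis(-1), plogis(1) - plogis(-1), 1 - plogis(1)),
               tolerance = 1e-12)
  expect_equal(categoryProbs(0, 0), c(0.5, 0.5))
  expect_error(categoryProbs(c(1, -1), 0), "increasing")
  # simplex property over random valid inputs
  set.seed(2)
  for (r in 1:50) {
    K <- sample(2:6, 1)
    alpha <- sort(rnorm(K - 1, 0, 3))
    pr <- categoryProbs(alpha, rnorm(1, 0, 4))
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
})

test_that("log-likelihood follows the alpha_k - beta'x parameterization", {
  set.seed(3)
  X <- standardizeFeatures(matrix(rnorm(60), 30, 2))
  y <- rep(1:3, each = 10)
  d <- ordinalDataset(X, y)
  st <- parameterState(c(-1, 1), c(0.4, -0.6))

  # per-observation values from the logistic-CDF oracle (p = 0, K = 3)
  d0 <- ordinalDataset(matrix(numeric(0), 3, 0), c(2L, 1L, 3L))
  expect_equal(logLikelihood(parameterState(c(-1, 1), numeric(0)), d0, "I"),
               log(plogis(1) - plogis(-1)) + log(plogis(-1)) +
                 log(1 - plogis(1)),
               tolerance = 1e-12)

  # additivity: duplicating every observation doubles the log-likelihood
  # (p = 0 so the duplicated matrix stays validly standardized)
  dI <- ordinalDataset(matrix(numeric(0), 30, 0), y)
  dII <- ordinalDataset(matrix(numeric(0), 60, 0), c(y, y))
  st0 <- parameterState(c(-0.7, 0.9), numeric(0))
  expect_equal(logLikelihood(st0, dII, "I"), 2 * logLikelihood(st0, dI, "I"),
               tolerance = 1e-10)
  # additivity against the per-observation category-probability oracle
  eta <- as.vector(X %*% st@beta)
  perObs <- vapply(seq_len(30), function(i)
    log(categoryProbs(st@alpha, eta[i])[y[i]]), numeric(1))
  expect_equal(logLikelihood(st, d, "I"), sum(perObs), tolerance = 1e-10)

  # invariance under permutation of observations
  perm <- sample(30)
  dp <- ordinalDataset(standardizeFeatures(X[perm, ]), y[perm])
  expect_equal(logLikelihood(st, dp, "I"), logLikelihood(st, d, "I"),
               tolerance = 1e-8)

  # Model IV with all-zero gamma is the intercept-only model
  st0 <- parameterState(c(-1, 1), c(5, -5), gamma = c(0, 0))
  ll0 <- sum(log(categoryProbs(c(-1, 1), 0))[y])
  expect_equal(logLikelihood(st0, d, "IV"), ll0, tolerance = 1e-10)

  # Model IV gamma gates each coefficient individually
  stg <- parameterState(c(-1, 1), c(0.4, -0.6), gamma = c(1, 0))
  stHalf <- parameterState(c(-1, 1), c(0.4, 0))
  expect_equal(logLikelihood(stg, d, "IV"), logLikelihood(stHalf, d, "I"))

  # model/state mismatches refuse
  expect_error(logLikelihood(stg, d, "I"), "gamma")
  expect_error(logLikelihood(st, d, "IV"), "gamma")
})

test_that("binary case reduces to the Bernoulli-logit log-likelihood", {
  set.seed(4)
  X <- standardizeFeatures(matrix(rnorm(80), 40, 2))
  y <- rep(1:2, 20)
  d <- ordinalDataset(X, y)
  st <- parameterState(0.3, c(0.8, -1.1))
  # independently coded: P(Y = 1) = plogis(alpha1 - eta)
  eta <- as.vector(X %*% st@beta)
  ll <- sum(ifelse(y == 1, plogis(0.3 - eta, log.p = TRUE),
                   plogis(-(0.3 - eta), log.p = TRUE)))
  expect_equal(logLikelihood(st, d, "I"), ll, tolerance = 1e-10)
})

test_that("domain objects enforce their invariants", {
  X <- standardizeFeatures(matrix(rnorm(40), 20, 2))
  expect_error(ordinalDataset(X, rep(c(1L, 3L), 10)),
               "category")                      # level 2 missing
  expect_error(ordinalDataset(matrix(rnorm(40), 20, 2), rep(1:2, 10)),
               "standardized")
  expect_error(ordinalDataset(X, c(rep(1:2, 9), NA, 2L)), "missing|NA")
  expect_error(parameterState(c(1, -1), c(0, 0)), "increasing")
  expect_error(parameterState(c(-1, 1), c(0, 0), gamma = c(2, 0)), "0 or 1")
  expect_error(priorSpec("II", sigma2_0 = 10, sigma2_1 = 0.01), "sigma2_0")
  expect_error(priorSpec("I", t = 1.5), "t must")
  expect_error(bfTest("gamma", epsilon = -1), "epsilon")
  # ordered labels map through the explicit level ordering
  d <- ordinalDataset(X, rep(c("low", "high"), 10),
                      levels = c("low", "high"))
  expect_identical(d@y[1:2], c(1L, 2L))
  expect_error(ordinalDataset(X, rep(c("low", "high"), 10),
                              levels = c("low", "mid")), "labels")
})
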