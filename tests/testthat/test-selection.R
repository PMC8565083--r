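test_that("marginal prior inclusion odds follow the pi specification", {
  expect_equal(priorOddsGamma(priorSpec("IV", t = 0.5)), 1)
  expect_equal(priorOddsGamma(priorSpec("II", t = 0.05)), 0.05 / 0.95,
               tolerance = 1e-12)
  expect_equal(priorOddsGamma(priorSpec("III", piMode = "beta", c = 1, d = 19)),
               1 / 19, tolerance = 1e-12)
  expect_equal(priorOddsGamma(priorSpec("IV", piMode = "beta",
                                        c = 0.01, d = 0.19)),
               1 / 19, tolerance = 1e-12)
  expect_error(priorOddsGamma(priorSpec("I")), "Model I")
})

test_that("closed-form interval-null prior tail probabilities", {
  # Model I: Gamma-mixed DE tail (b/(b+eps))^a
  expect_equal(priorProbBetaExceeds(priorSpec("I"), 0.1), 2^-0.1,
               tolerance = 1e-12)
  # continuous priors put no mass at zero: eps -> 0+ gives 1
  for (m in c("I", "II", "III"))
    expect_equal(priorProbBetaExceeds(priorSpec(m, t = 0.3), 1e-12), 1,
                 tolerance = 1e-6)
  # Model II with pibar ~ 0 is the pure spike tail 2*Phi(-1)
  expect_equal(priorProbBetaExceeds(priorSpec("II", t = 1e-12), 0.1),
               2 * pnorm(-1), tolerance = 1e-9)
  # Model II mixes the two normal tails by pibar
  expect_equal(priorProbBetaExceeds(priorSpec("II", t = 0.5), 0.1),
               0.5 * 2 * pnorm(-0.1 / 0.1) + 0.5 * 2 * pnorm(-0.1 / sqrt(10)),
               tolerance = 1e-12)
  # Model III mixes the spike DE tail with the Gamma-mixed slab tail
  expect_equal(priorProbBetaExceeds(priorSpec("III", t = 0.05), 0.1),
               0.95 * exp(-2) + 0.05 * 2^-0.1, tolerance = 1e-12)
  # Model IV: indicator zero contributes exactly-null mass
  expect_equal(priorProbGammaBetaExceeds(priorSpec("IV", t = 0.05), 0.1),
               0.05 * 2^-0.1, tolerance = 1e-12)
  expect_equal(priorProbGammaBetaExceeds(priorSpec("IV", t = 1 - 1e-12), 0.1),
               priorProbBetaExceeds(priorSpec("I"), 0.1), tolerance = 1e-9)
  expect_error(priorProbBetaExceeds(priorSpec("I"), -0.1), "epsilon")
  expect_error(priorProbBetaExceeds(priorSpec("IV"), 0.1), "Model IV")
  expect_error(priorProbGammaBetaExceeds(priorSpec("I"), 0.1), "Model IV")
})

test_that("empirical posterior odds use the continuity-corrected count rule", {
  g <- c(rep(1, 250), rep(0, 250))
  s <- fakeSamples(beta = matrix(rnorm(500), 500, 1), gamma = cbind(g))
  # m = N/2: the correction cancels
  expect_equal(posteriorOdds(s, 1, bfTest("gamma")), 1)
  # all-one indicator chain: (N + 1/2) / (1/2)
  s1 <- fakeSamples(beta = matrix(rnorm(500), 500, 1), gamma = cbind(rep(1, 500)))
  expect_equal(posteriorOdds(s1, 1, bfTest("gamma")), 500.5 / 0.5)
  expect_equal(posteriorOdds(s1, 1, bfTest("gamma"), correction = FALSE), Inf)
  # all-zero indicator chain stays finite under the correction
  s0 <- fakeSamples(beta = matrix(rnorm(500), 500, 1), gamma = cbind(rep(0, 500)))
  expect_equal(posteriorOdds(s0, 1, bfTest("gamma")), 0.5 / 500.5)
  # beta interval test counts |draws| > epsilon (Model I)
  b <- c(rep(0.5, 100), rep(0.01, 300), rep(-3, 100))
  sb <- fakeSamples(beta = cbind(b))
  expect_equal(posteriorOdds(sb, 1, bfTest("beta", epsilon = 0.1)),
               200.5 / 300.5)
  # Model IV interval test uses gamma * beta
  sgb <- fakeSamples(beta = cbind(rep(2, 500)),
                     gamma = cbind(c(rep(1, 100), rep(0, 400))))
  expect_equal(posteriorOdds(sgb, 1, bfTest("beta", epsilon = 0.1)),
               100.5 / 400.5)
  expect_error(posteriorOdds(fakeSamples(beta = cbind(rnorm(500))), 1,
                             bfTest("gamma")), "Model I")
})

test_that("Bayes factor is posterior odds over prior odds with strict rejection", {
  set.seed(10)
  g <- cbind(rbinom(500, 1, 0.6), rbinom(500, 1, 0.1))
  s <- fakeSamples(beta = matrix(rnorm(1000), 500, 2), gamma = g,
                   prior = priorSpec("IV", t = 0.05))
  tab <- bayesFactors(s, bfTest("gamma"))
  expect_equal(tab$bf, tab$posterior_odds / tab$prior_odds, tolerance = 1e-12)
  expect_identical(tab$rejected, tab$bf > 5)
  # posterior odds of 1 under t = 0.05 gives BF = 19 > 5
  g1 <- cbind(c(rep(1, 250), rep(0, 250)))
  s1 <- fakeSamples(beta = cbind(rnorm(500)), gamma = g1,
                    prior = priorSpec("IV", t = 0.05))
  t1 <- bayesFactors(s1, bfTest("gamma"))
  expect_equal(t1$bf, 19)
  expect_true(t1$rejected)
  # posterior odds equal to prior odds: BF = 1 for any prior
  sEq <- fakeSamples(beta = cbind(rnorm(500)), gamma = g1,
                     prior = priorSpec("IV", t = 0.5))
  expect_equal(bayesFactors(sEq, bfTest("gamma"))$bf, 1)
  expect_error(bayesFactors(fakeSamples(beta = cbind(rnorm(500))),
                            bfTest("gamma")), "Model I")
})

test_that("feature selection respects the strict threshold and nests", {
  mk <- function(bfs, thr = 5) {
    tab <- data.frame(feature_id = paste0("f", seq_along(bfs)),
                      prior_odds = 1, posterior_odds = bfs, bf = bfs,
                      rejected = bfs > thr, stringsAsFactors = FALSE)
    attr(tab, "test") <- bfTest("gamma", bfThreshold = thr)
    tab
  }
  sel <- selectFeatures(mk(c(19, 4.9, 5.0)))
  expect_identical(sel$feature_id, "f1")           # 5.0 is not > 5
  expect_identical(nrow(selectFeatures(mk(c(1, 2, 4.99)))), 0L)
  # selected set non-increasing in the threshold
  bfs <- c(19, 7, 5.5, 2, 0.3)
  s10 <- selectFeatures(mk(bfs, 10))$feature_id
  s3 <- selectFeatures(mk(bfs, 3))$feature_id
  expect_true(all(s10 %in% s3))
  # sorted by decreasing BF
  expect_identical(selectFeatures(mk(c(6, 60, 8)))$bf, c(60, 8, 6))
  bad <- list(mk(c(1, 10)), mk(c(1, 10), thr = 3))
  expect_error(selectFeatures(bad), "one test spec")
})

test_that("epsilon monotonicity: larger interval nulls reject fewer features", {
  set.seed(11)
  b <- matrix(rnorm(1000, 0, 0.5), 500, 2)
  s <- fakeSamples(beta = b)
  for (j in 1:2) {
    oddsSmall <- posteriorOdds(s, j, bfTest("beta", epsilon = 0.05))
    oddsLarge <- posteriorOdds(s, j, bfTest("beta", epsilon = 0.3))
    expect_gte(oddsSmall, oddsLarge)
  }
})

test_that("credible intervals: equal-tailed quantiles and shortest HPD window", {
  draws <- seq(0, 1, length.out = 1001)
  et <- credibleInterval(draws, 0.95, "ET")
  expect_equal(et, c(0.025, 0.975), tolerance = 2 / 1001)
  # symmetric unimodal draws: HPD ~= ET
  set.seed(12)
  z <- rnorm(50000)
  expect_equal(credibleInterval(z, 0.95, "HPD"),
               credibleInterval(z, 0.95, "ET"), tolerance = 0.06)
  # a skewed sample has a shorter HPD than ET
  g <- rgamma(50000, 2, 1)
  hpd <- credibleInterval(g, 0.95, "HPD"); etg <- credibleInterval(g, 0.95, "ET")
  expect_lt(diff(hpd), diff(etg))
  expect_gte(mean(g >= hpd[1] & g <= hpd[2]), 0.95 - 1e-4)
  # degenerate draws collapse both intervals
  cc <- rep(3.2, 200)
  expect_equal(credibleInterval(cc, 0.95, "ET"), c(3.2, 3.2))
  expect_equal(credibleInterval(cc, 0.95, "HPD"), c(3.2, 3.2))
  expect_error(credibleInterval(rnorm(50), 0.95), "100")
  expect_error(credibleInterval(z, 1.2), "level")
})

test_that("interval selection flags features whose interval excludes zero", {
  sPos <- fakeSamples(beta = cbind(runif(500, 0.2, 0.9)))
  expect_true(selectByInterval(sPos, 1, 0.95, "ET"))
  sSpan <- fakeSamples(beta = cbind(runif(500, -0.1, 0.3)))
  expect_false(selectByInterval(sSpan, 1, 0.95, "ET"))
  # Model IV: gamma zeros put mass at 0 in gamma*beta, pulling intervals to 0
  set.seed(13)
  sIV <- fakeSamples(beta = cbind(rnorm(500, 2, 0.1)),
                     gamma = cbind(rbinom(500, 1, 0.5)),
                     prior = priorSpec("IV", t = 0.5))
  expect_false(selectByInterval(sIV, 1, 0.95, "HPD"))
  sIVhi <- fakeSamples(beta = cbind(rnorm(500, 2, 0.1)),
                       gamma = cbind(rbinom(500, 1, 0.99)),
                       prior = priorSpec("IV", t = 0.5))
  expect_true(selectByInterval(sIVhi, 1, 0.95, "HPD"))
})
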