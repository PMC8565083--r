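#' Marginal prior odds of inclusion, P(gamma_j = 1) / P(gamma_j = 0)
#'
#' Under piMode = "fixed" this is t / (1 - t); under the Beta(c, d)
#' hyperprior the marginal inclusion probability is c / (c + d), giving
#' prior odds c / d. Model I has no inclusion indicator.
#'
#' @param prior a [PriorSpec-class] with model "II", "III" or "IV".
#' @return positive prior odds.
#' @examples
#' priorOddsGamma(priorSpec("IV", t = 0.05))              # 1/19
#' priorOddsGamma(priorSpec("IV", piMode = "beta", c = 1, d = 19))
#' @export
priorOddsGamma <- function(prior) {
  stopifnot(is(prior, "PriorSpec"))
  if (prior@model == "I") stop("Model I has no gamma")
  if (prior@piMode == "fixed") prior@t / (1 - prior@t) else prior@c / prior@d
}

#' Marginal prior probability that |beta_j| exceeds epsilon
#'
#' Closed forms for the interval-null prior mass under each coefficient
#' prior, marginalized over lambda and pi:
#' \itemize{
#'   \item Model I: the DE(lambda) tail e^{-lambda epsilon} mixed over
#'     lambda ~ Gamma(a, b) gives (b / (b + epsilon))^a.
#'   \item Model II: (1 - pibar) 2 Phi(-epsilon / sigma_0) +
#'     pibar 2 Phi(-epsilon / sigma_1).
#'   \item Model III: (1 - pibar) e^{-lambda_0 epsilon} +
#'     pibar (b / (b + epsilon))^a.
#' }
#' with pibar the marginal mean of pi_j. For Model IV use
#' [priorProbGammaBetaExceeds()].
#'
#' @param prior a [PriorSpec-class] with model "I", "II" or "III".
#' @param epsilon interval half-width, > 0.
#' @return prior probability in (0, 1).
#' @export
priorProbBetaExceeds <- function(prior, epsilon = 0.10) {
  stopifnot(is(prior, "PriorSpec"))
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (prior@model == "IV")
    stop("Model IV tests |gamma_j beta_j|; use priorProbGammaBetaExceeds()")
  deTail <- (prior@b / (prior@b + epsilon))^prior@a
  switch(prior@model,
    I = deTail,
    II = {
      pibar <- priorMeanPi(prior)
      (1 - pibar) * 2 * stats::pnorm(-epsilon / sqrt(prior@sigma2_0)) +
        pibar * 2 * stats::pnorm(-epsilon / sqrt(prior@sigma2_1))
    },
    III = {
      pibar <- priorMeanPi(prior)
      (1 - pibar) * exp(-prior@lambda0 * epsilon) + pibar * deTail
    })
}

#' Marginal prior probability that |gamma_j beta_j| exceeds epsilon (Model IV)
#'
#' With probability 1 - pibar the indicator is 0 and gamma_j beta_j is
#' exactly 0, inside the null; otherwise the DE-Gamma tail applies, giving
#' pibar (b / (b + epsilon))^a.
#'
#' @inheritParams priorProbBetaExceeds
#' @return prior probability in (0, 1).
#' @export
priorProbGammaBetaExceeds <- function(prior, epsilon = 0.10) {
  stopifnot(is(prior, "PriorSpec"))
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (prior@model != "IV")
    stop("only Model IV tests |gamma_j beta_j|")
  priorMeanPi(prior) * (prior@b / (prior@b + epsilon))^prior@a
}

# prior odds for a given test spec under a given prior
priorOddsFor <- function(prior, test) {
  if (test@test == "gamma") return(priorOddsGamma(prior))
  pr <- if (prior@model == "IV")
    priorProbGammaBetaExceeds(prior, test@epsilon)
  else priorProbBetaExceeds(prior, test@epsilon)
  pr / (1 - pr)
}

#' Empirical posterior odds of the alternative from MCMC draws
#'
#' Pools post burn-in draws across chains and counts the draws satisfying
#' the alternative: gamma_j = 1 (test = "gamma"), |beta_j| > epsilon
#' (test = "beta", Models I-III) or |gamma_j beta_j| > epsilon (Model IV).
#' With m of N draws in the alternative, the continuity-corrected odds are
#' (m + 1/2) / (N - m + 1/2), which stay finite when the indicator chain is
#' stuck at 0 or 1; `correction = FALSE` gives the raw m / (N - m).
#'
#' @param samples a [PosteriorSamples-class].
#' @param feature feature index or id.
#' @param test a [BFTest-class].
#' @param correction apply the continuity correction (default TRUE).
#' @return non-negative posterior odds.
#' @export
posteriorOdds <- function(samples, feature, test = bfTest("gamma"),
                          correction = TRUE) {
  stopifnot(is(samples, "PosteriorSamples"), is(test, "BFTest"))
  if (test@test == "gamma") {
    if (samples@model == "I")
      stop("Model I has no gamma; only the beta interval test is available")
    g <- pooledDraws(samples, "gamma", feature)
    m <- sum(g == 1)
    N <- length(g)
  } else {
    dr <- if (samples@model == "IV")
      pooledDraws(samples, "gammabeta", feature)
    else pooledDraws(samples, "beta", feature)
    m <- sum(abs(dr) > test@epsilon)
    N <- length(dr)
  }
  if (N == 0L) stop("no draws available")
  if (correction) (m + 0.5) / (N - m + 0.5) else m / (N - m)
}

#' Bayes-factor variable selection table
#'
#' For every feature computes the prior odds (closed form from the prior
#' specification), the empirical posterior odds from the pooled MCMC draws,
#' their ratio B10, and the rejection decision B10 > threshold (strict).
#' Model I supports only the "beta" interval test.
#'
#' @param samples a [PosteriorSamples-class].
#' @param test a [BFTest-class].
#' @param correction continuity-correct the posterior odds (default TRUE).
#' @return data.frame with columns `feature_id`, `prior_odds`,
#'   `posterior_odds`, `bf`, `rejected`, in the original feature order, with
#'   the test spec attached as attribute "test".
#' @examples
#' \donttest{
#' sim <- simulateOrdinal(n = 80, p = 5, supportSize = 1, effect = 2, seed = 2)
#' fit <- fitBayesOrdinal(sim$data, priorSpec("IV", t = 0.05),
#'                        mcmcControl(nChains = 2, nBurnin = 200, nAdapt = 200,
#'                                    thin = 1, nSavedTotal = 600))
#' bayesFactors(fit, bfTest("gamma"))
#' }
#' @export
bayesFactors <- function(samples, test = bfTest("gamma"), correction = TRUE) {
  stopifnot(is(samples, "PosteriorSamples"), is(test, "BFTest"))
  prior <- samples@prior
  if (test@test == "gamma" && samples@model == "I")
    stop("Model I has no gamma; only the beta interval test is available")
  p <- dim(samples@beta)[3L]
  po <- priorOddsFor(prior, test)
  post <- vapply(seq_len(p), function(j)
    posteriorOdds(samples, j, test, correction), numeric(1))
  bf <- post / po
  out <- data.frame(
    feature_id = samples@featureIds,
    prior_odds = rep(po, p),
    posterior_odds = post,
    bf = bf,
    rejected = bf > test@bfThreshold,
    stringsAsFactors = FALSE)
  attr(out, "test") <- test
  out
}

#' Features selected by the Bayes-factor rule
#'
#' Filters a [bayesFactors()] table to the rejected features, sorted by
#' decreasing Bayes factor. All supplied results must share one test spec.
#'
#' @param results a [bayesFactors()] data.frame, or a list of such
#'   data.frames sharing an identical test spec (rows are concatenated).
#' @return data.frame of selected features sorted by decreasing `bf`.
#' @export
selectFeatures <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  specs <- lapply(results, attr, "test")
  first <- specs[[1L]]
  same <- vapply(specs, function(s)
    !is.null(s) && identical(s@test, first@test) &&
      s@epsilon == first@epsilon && s@bfThreshold == first@bfThreshold,
    logical(1))
  if (!all(same)) stop("all results must share one test spec")
  tab <- do.call(rbind, results)
  tab <- tab[tab$rejected, , drop = FALSE]
  tab <- tab[order(-tab$bf), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "test") <- first
  tab
}

#' Credible interval from posterior draws of a scalar
#'
#' Equal-tailed ("ET") intervals use empirical quantiles at (1 - level)/2
#' and (1 + level)/2; "HPD" returns the shortest contiguous interval
#' containing ceiling(level * N) sorted draws (assumes a unimodal
#' posterior).
#'
#' @param draws numeric vector, at least 100 draws.
#' @param level coverage level in (0, 1), default 0.95.
#' @param kind "ET" or "HPD".
#' @return numeric c(lower, upper).
#' @export
credibleInterval <- function(draws, level = 0.95, kind = c("ET", "HPD")) {
  kind <- match.arg(kind)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  if (length(draws) < 100L) stop("need at least 100 draws")
  if (kind == "ET") {
    unname(stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2)))
  } else {
    s <- sort(draws)
    N <- length(s)
    m <- ceiling(level * N)
    if (m >= N) return(c(s[1L], s[N]))
    i <- seq_len(N - m + 1L)
    widths <- s[i + m - 1L] - s[i]
    lo <- which.min(widths)
    c(s[lo], s[lo + m - 1L])
  }
}

#' Interval-based selection of a single feature
#'
#' TRUE when the credible interval for beta_j (Models I-III) or
#' gamma_j beta_j (Model IV) does not include zero.
#'
#' @param samples a [PosteriorSamples-class].
#' @param feature feature index or id.
#' @param level coverage level, default 0.95.
#' @param kind "ET" or "HPD".
#' @return logical.
#' @export
selectByInterval <- function(samples, feature, level = 0.95,
                             kind = c("ET", "HPD")) {
  kind <- match.arg(kind)
  dr <- if (samples@model == "IV")
    pooledDraws(samples, "gammabeta", feature)
  else pooledDraws(samples, "beta", feature)
  ci <- credibleInterval(dr, level, kind)
  ci[1L] > 0 || ci[2L] < 0
}
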