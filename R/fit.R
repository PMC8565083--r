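#' Fit a penalized Bayesian cumulative-logit model by MCMC
#'
#' Draws from the joint posterior of the chosen model variant using a
#' slice-within-Gibbs sampler: univariate slice updates for each threshold
#' alpha_k (restricted to its ordering interval) and each coefficient beta_j,
#' with conjugate Gibbs updates for lambda, the inclusion indicators gamma
#' and (under piMode = "beta") the feature-specific pi_j. Slice widths adapt
#' during the first `nAdapt` iterations and are then frozen; adaptation and
#' burn-in draws are discarded. Chains share the data and differ only through
#' seed-derived initial states (thresholds are initialized at the empirical
#' logit cumulative frequencies and jittered per chain).
#'
#' Identical `(data, prior, control)` inputs give bit-identical output.
#'
#' @param data an [OrdinalDataset-class]; columns of X must be standardized.
#'   p = 0 gives an intercept-only fit.
#' @param prior a [PriorSpec-class] selecting the model variant.
#' @param control an [MCMCControl-class].
#' @return A [PosteriorSamples-class] with draw arrays indexed
#'   [chain, iteration, parameter].
#' @examples
#' sim <- simulateOrdinal(n = 60, p = 4, supportSize = 1, effect = 2, seed = 1)
#' fit <- fitBayesOrdinal(sim$data, priorSpec("IV", t = 0.5),
#'                        mcmcControl(nChains = 2, nBurnin = 100, nAdapt = 100,
#'                                    thin = 1, nSavedTotal = 200))
#' @export
fitBayesOrdinal <- function(data, prior = priorSpec("I"),
                            control = mcmcControl()) {
  stopifnot(is(data, "OrdinalDataset"), is(prior, "PriorSpec"),
            is(control, "MCMCControl"))
  validObject(data)  # refuses missing categories / unstandardized X
  X <- data@X
  y <- data@y
  K <- data@K
  p <- ncol(X)
  model <- match(prior@model, c("I", "II", "III", "IV"))
  priorList <- list(
    model = as.integer(model), a = prior@a, b = prior@b,
    sigma2Alpha = as.numeric(prior@sigma2Alpha), sigma2_0 = prior@sigma2_0,
    sigma2_1 = prior@sigma2_1, lambda0 = prior@lambda0,
    piMode = as.integer(prior@piMode == "beta"), t = prior@t,
    c = prior@c, d = prior@d)
  if (length(prior@sigma2Alpha) > 1L && length(prior@sigma2Alpha) != K - 1L)
    stop("sigma2Alpha must be scalar or length K-1")
  nChains <- control@nChains
  nSave <- ceiling(control@nSavedTotal / nChains)
  pibar <- priorMeanPi(prior)

  # empirical logit cumulative frequencies as the alpha backbone
  cumfreq <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / length(y)
  alpha0 <- stats::qlogis(pmin(pmax(cumfreq, 1e-3), 1 - 1e-3))

  set.seed(control@seed)
  chains <- vector("list", nChains)
  for (ch in seq_len(nChains)) {
    al <- alpha0 + stats::rnorm(K - 1L, 0, 0.3)
    al <- sort(al)
    if (any(diff(al) < 1e-3))
      al <- al + seq(0, by = 1e-3, length.out = K - 1L)
    init <- list(alpha = al, beta = rep(0, p))
    if (model >= 2) {
      init$gamma <- as.integer(stats::rbinom(p, 1L, pibar))
      if (prior@piMode == "beta") init$pi <- rep(pibar, p)
    }
    if (model != 2) init$lambda <- prior@a / prior@b
    chains[[ch]] <- .bvs_run_chain(X, y, as.integer(K), priorList, init,
                                   control@nAdapt, control@nBurnin,
                                   control@thin, as.integer(nSave))
  }

  bindChains <- function(name, integerOk = FALSE) {
    if (is.null(chains[[1L]][[name]])) return(NULL)
    first <- chains[[1L]][[name]]
    if (is.matrix(first)) {
      d3 <- ncol(first)
      arr <- array(0, dim = c(nChains, nSave, d3))
      for (ch in seq_len(nChains)) arr[ch, , ] <- chains[[ch]][[name]]
      arr
    } else {
      arr <- array(0, dim = c(nChains, nSave))
      for (ch in seq_len(nChains)) arr[ch, ] <- chains[[ch]][[name]]
      arr
    }
  }

  new("PosteriorSamples",
      model = prior@model,
      alpha = bindChains("alpha"),
      beta = bindChains("beta"),
      gamma = bindChains("gamma"),
      pi = bindChains("pi"),
      lambda = bindChains("lambda"),
      featureIds = data@featureIds,
      prior = prior, control = control)
}

# One Gibbs sweep of the fitting kernel from an explicit state; exposed for
# kernel-validation (successive-conditional) experiments and tests.
#' Advance the sampler by one Gibbs sweep
#'
#' Applies exactly one sweep of the MCMC kernel used by [fitBayesOrdinal()]
#' (slice updates for alpha and beta, conjugate updates for gamma, lambda,
#' pi) to an explicit parameter state. The kernel leaves the joint posterior
#' invariant; this entry point exists so that the property can be tested.
#'
#' @param state named list with elements `alpha`, `beta` and, as required by
#'   the variant, `gamma`, `lambda`, `pi`.
#' @param X standardized feature matrix (raw matrix, so that responses with
#'   an unobserved category are usable in validation runs).
#' @param y integer response in 1..K.
#' @param K number of categories.
#' @param prior a [PriorSpec-class].
#' @return the updated state as a named list.
#' @export
oneGibbsSweep <- function(state, X, y, K, prior) {
  model <- match(prior@model, c("I", "II", "III", "IV"))
  priorList <- list(
    model = as.integer(model), a = prior@a, b = prior@b,
    sigma2Alpha = as.numeric(prior@sigma2Alpha), sigma2_0 = prior@sigma2_0,
    sigma2_1 = prior@sigma2_1, lambda0 = prior@lambda0,
    piMode = as.integer(prior@piMode == "beta"), t = prior@t,
    c = prior@c, d = prior@d)
  st <- state
  if (model >= 2) st$gamma <- as.integer(st$gamma)
  .bvs_one_sweep(as.matrix(X), as.integer(y), as.integer(K), priorList, st)
}
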