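#' Full-conditional Gamma parameters for the LASSO rate lambda
#'
#' The double-exponential prior beta_j | lambda ~ DE(0, 1/lambda) with
#' lambda ~ Gamma(a, b) is conjugate: the full conditional of lambda is
#' Gamma(a + m, b + S). For Models I and IV every coefficient carries the
#' DE(lambda) prior, so m = p and S = sum_j |beta_j|; for Model III only
#' slab coefficients (gamma_j = 1) involve lambda (the spike uses the fixed
#' rate lambda0), so m = sum_j gamma_j and S sums |beta_j| over the slab.
#' Model II has no lambda.
#'
#' @param beta coefficient vector.
#' @param gamma 0/1 indicator vector (Model III) or NULL.
#' @param model "I", "III" or "IV".
#' @param a,b Gamma hyperparameters.
#' @return `lambdaPosterior`: named vector c(shape, rate).
#' @export
lambdaPosterior <- function(beta, gamma = NULL, model = c("I", "III", "IV"),
                            a = 0.1, b = 0.1) {
  model <- match.arg(model)
  if (model == "III") {
    if (is.null(gamma)) stop("Model III requires gamma")
    sel <- gamma == 1
    c(shape = a + sum(sel), rate = b + sum(abs(beta[sel])))
  } else {
    c(shape = a + length(beta), rate = b + sum(abs(beta)))
  }
}

#' @rdname lambdaPosterior
#' @return `updateLambda`: one draw from the full conditional.
#' @export
updateLambda <- function(beta, gamma = NULL, model = c("I", "III", "IV"),
                         a = 0.1, b = 0.1) {
  if (length(model) == 1L && model == "II") stop("Model II has no lambda")
  model <- match.arg(model)
  par <- lambdaPosterior(beta, gamma, model, a, b)
  stats::rgamma(1L, shape = par["shape"], rate = par["rate"])
}

#' Conditional inclusion probability P(gamma_j = 1 | rest)
#'
#' For Models II and III the indicator enters only the prior mixture (beta_j
#' stays in the likelihood either way), so the conditional is
#' pi_j f1(beta_j) / (pi_j f1(beta_j) + (1 - pi_j) f0(beta_j)) with f0/f1
#' the spike/slab densities. For Model IV the feature is omitted from the
#' linear predictor when gamma_j = 0, so the conditional additionally
#' multiplies the slab term by the likelihood ratio
#' R = L(gamma_j = 1 | rest) / L(gamma_j = 0 | rest), which must be supplied.
#'
#' @param betaJ current coefficient value.
#' @param piJ inclusion probability in (0, 1).
#' @param prior a [PriorSpec-class] (Models II-IV).
#' @param lambda current LASSO rate (Model III slab density).
#' @param likelihoodRatio likelihood ratio R (Model IV only).
#' @return probability that gamma_j = 1.
#' @examples
#' gammaInclusionProb(0, 0.5, priorSpec("II"))          # ~0.0307
#' gammaInclusionProb(0, 0.5, priorSpec("III"), lambda = 1)  # 1/21
#' @export
gammaInclusionProb <- function(betaJ, piJ, prior, lambda = NULL,
                               likelihoodRatio = NULL) {
  stopifnot(is(prior, "PriorSpec"))
  if (piJ <= 0 || piJ >= 1) stop("piJ must lie in (0, 1)")
  model <- prior@model
  if (model == "I") stop("Model I has no gamma")
  logRatio10 <- switch(model,  # log f1(beta) - log f0(beta) [+ log R]
    II = stats::dnorm(betaJ, 0, sqrt(prior@sigma2_1), log = TRUE) -
         stats::dnorm(betaJ, 0, sqrt(prior@sigma2_0), log = TRUE),
    III = {
      if (is.null(lambda)) stop("Model III requires the current lambda")
      (log(lambda / 2) - lambda * abs(betaJ)) -
        (log(prior@lambda0 / 2) - prior@lambda0 * abs(betaJ))
    },
    IV = {
      if (is.null(likelihoodRatio))
        stop("Model IV requires the likelihood ratio")
      log(likelihoodRatio)  # beta prior identical under both indicator values
    })
  stats::plogis(logRatio10 + stats::qlogis(piJ))
}

#' Beta-Bernoulli update of a feature-specific inclusion probability
#'
#' Under piMode = "beta" each pi_j has its own Beta(c, d) prior and governs a
#' single Bernoulli trial gamma_j, so the full conditional is
#' Beta(c + gamma_j, d + 1 - gamma_j). Under piMode = "fixed" pi is a
#' constant and is never updated.
#'
#' @param gammaJ current indicator value, 0 or 1.
#' @param c,d Beta hyperparameters.
#' @return `piPosterior`: named vector c(shape1, shape2).
#' @export
piPosterior <- function(gammaJ, c = 1, d = 19) {
  if (!gammaJ %in% c(0, 1)) stop("gammaJ must be 0 or 1")
  c(shape1 = c + gammaJ, shape2 = d + 1 - gammaJ)
}

#' @rdname piPosterior
#' @param prior optional [PriorSpec-class]; if supplied with
#'   piMode = "fixed" the update errors, since pi is then a constant.
#' @return `updatePi`: one draw in (0, 1).
#' @export
updatePi <- function(gammaJ, c = 1, d = 19, prior = NULL) {
  if (!is.null(prior) && prior@piMode == "fixed")
    stop("pi is fixed at t under piMode='fixed' and is never updated")
  par <- piPosterior(gammaJ, c, d)
  stats::rbeta(1L, par["shape1"], par["shape2"])
}
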