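#' Cumulative probability of the proportional-odds model
#'
#' Evaluates P(Y <= k | x) = exp(alpha_k - eta) / (1 + exp(alpha_k - eta))
#' under the cumulative-logit model, where eta = beta'x is the linear
#' predictor. Computed through a branch-stable logistic CDF so that
#' |alpha_k - eta| > 30 does not overflow.
#'
#' @param alphaK threshold alpha_k (finite numeric, vectorized).
#' @param eta linear predictor (finite numeric, vectorized).
#' @return P(Y <= k | x), strictly increasing in `alphaK` and strictly
#'   decreasing in `eta`.
#' @examples
#' cumulativeProb(0, 0)   # 0.5
#' cumulativeProb(1, 0)   # exp(1)/(1 + exp(1))
#' @export
cumulativeProb <- function(alphaK, eta) {
  if (!all(is.finite(alphaK)) || !all(is.finite(eta)))
    stop("alphaK and eta must be finite")
  stats::plogis(alphaK - eta)
}

#' Category probabilities from thresholds and a linear predictor
#'
#' First differences of the cumulative probabilities: the probability that
#' the latent logistic variable Z = eta + logistic noise falls in
#' (alpha_{k-1}, alpha_k].
#'
#' @param alpha strictly increasing thresholds, length K-1.
#' @param eta scalar linear predictor.
#' @return numeric vector of length K, non-negative, summing to 1.
#' @examples
#' categoryProbs(c(-1, 1), 0)
#' @export
categoryProbs <- function(alpha, eta) {
  if (!all(is.finite(alpha)) || !is.finite(eta))
    stop("alpha and eta must be finite")
  if (length(alpha) > 1L && any(diff(alpha) <= 0))
    stop("alpha must be strictly increasing")
  cp <- stats::plogis(alpha - eta)
  p <- diff(c(0, cp, 1))
  pmax(p, 0)
}

# stable log of P(Y = k | alpha, eta), vectorized over observations
logCategoryProb <- function(y, alpha, eta, K) {
  lF <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))
  out <- numeric(length(y))
  low <- y == 1L
  high <- y == K
  mid <- !(low | high)
  out[low] <- lF(alpha[1L] - eta[low])
  out[high] <- lF(eta[high] - alpha[K - 1L])
  if (any(mid)) {
    bu <- alpha[y[mid]] - eta[mid]
    bl <- alpha[y[mid] - 1L] - eta[mid]
    out[mid] <- lF(bu) + lF(-bl) + log1p(-exp(bl - bu))
  }
  out
}

#' Log-likelihood of the cumulative-logit model
#'
#' For Models I-III the linear predictor is eta_i = sum_j beta_j x_ij; for
#' Model IV it is eta_i = sum_j gamma_j beta_j x_ij, so that a feature with
#' gamma_j = 0 is omitted from the model. The sign convention is
#' alpha_k - beta'x: larger beta'x pushes mass toward higher categories.
#'
#' @param state a [ParameterState-class]; must carry gamma for Model IV and
#'   must not carry gamma for Model I.
#' @param data an [OrdinalDataset-class].
#' @param model model variant "I", "II", "III" or "IV".
#' @return finite log-likelihood value.
#' @examples
#' X <- standardizeFeatures(matrix(rnorm(30), 15, 2))
#' d <- ordinalDataset(X, rep(1:3, 5))
#' logLikelihood(parameterState(c(-1, 1), c(0.5, -0.5)), d, "I")
#' @export
logLikelihood <- function(state, data, model = c("I", "II", "III", "IV")) {
  model <- match.arg(model)
  stopifnot(is(state, "ParameterState"), is(data, "OrdinalDataset"))
  if (length(state@alpha) != data@K - 1L)
    stop("alpha must have length K-1")
  if (length(state@beta) != ncol(data@X))
    stop("beta must have length p")
  if (model == "I" && length(state@gamma))
    stop("Model I has no gamma; state carries inclusion indicators")
  if (model == "IV" && !length(state@gamma))
    stop("Model IV requires gamma in the state")
  coef <- if (model == "IV") state@gamma * state@beta else state@beta
  eta <- if (ncol(data@X)) as.vector(data@X %*% coef) else numeric(nrow(data@X))
  sum(logCategoryProb(data@y, state@alpha, eta, data@K))
}
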