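#' Construct an OrdinalDataset
#'
#' Builds the (X, y) container consumed by [fitBayesOrdinal()]. The response
#' may be supplied as an integer vector in 1..K, as a factor, or as a
#' character vector together with an explicit `levels` ordering (lowest
#' category first) -- the ordering is assumed known, e.g. favorable <
#' intermediate < adverse prognostic risk.
#'
#' @param X numeric matrix, n samples by p features. Must already be
#'   standardized (see [standardizeFeatures()]) unless `standardize = TRUE`.
#' @param y response: integer in 1..K, factor, or character.
#' @param levels ordered category labels, lowest first. Required when `y` is
#'   character; defaults to the factor levels or `as.character(1:K)`.
#' @param featureIds feature identifiers; defaults to `colnames(X)` or
#'   `"V1"..."Vp"`.
#' @param standardize if TRUE, center and scale columns of `X` first.
#' @return An [OrdinalDataset-class] object.
#' @examples
#' X <- standardizeFeatures(matrix(rnorm(40), 20, 2))
#' d <- ordinalDataset(X, rep(1:2, 10))
#' @export
ordinalDataset <- function(X, y, levels = NULL, featureIds = NULL,
                           standardize = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (is.character(y)) {
    if (is.null(levels))
      stop("character y requires an explicit ordered 'levels' vector")
    if (!all(y %in% levels)) stop("y contains labels not present in 'levels'")
    y <- as.integer(factor(y, levels = levels))
  } else if (is.factor(y)) {
    if (is.null(levels)) levels <- base::levels(y)
    y <- as.integer(factor(as.character(y), levels = levels))
  } else {
    y <- as.integer(y)
  }
  K <- max(y)
  if (is.null(levels)) levels <- as.character(seq_len(K))
  if (is.null(featureIds))
    featureIds <- if (!is.null(colnames(X))) colnames(X) else
      if (ncol(X)) paste0("V", seq_len(ncol(X))) else character(0)
  if (standardize && ncol(X)) X <- standardizeFeatures(X)
  new("OrdinalDataset", X = X, y = y, K = as.integer(K),
      featureIds = as.character(featureIds), levels = as.character(levels))
}

#' Construct a PriorSpec
#'
#' @param model model variant: "I" (Bayesian LASSO), "II" (spike-and-slab
#'   normal), "III" (spike-and-slab LASSO), "IV" (inclusion-indicator
#'   regression).
#' @param a,b Gamma(a, b) shape/rate hyperprior on the LASSO rate lambda.
#' @param sigma2Alpha prior variance of each threshold alpha_k; a scalar is
#'   shared across k, or supply a length K-1 vector.
#' @param sigma2_0,sigma2_1 Model II spike and slab variances.
#' @param lambda0 Model III spike double-exponential rate.
#' @param piMode "fixed" (pi_j = t for all j) or "beta" (pi_j ~ Beta(c, d)).
#' @param t fixed inclusion probability.
#' @param c,d Beta hyperparameters.
#' @return A [PriorSpec-class] object.
#' @examples
#' priorSpec("IV", piMode = "fixed", t = 0.05)
#' priorSpec("II", piMode = "beta", c = 1, d = 19)
#' @export
priorSpec <- function(model = c("I", "II", "III", "IV"), a = 0.1, b = 0.1,
                      sigma2Alpha = 10, sigma2_0 = 0.01, sigma2_1 = 10,
                      lambda0 = 20, piMode = c("fixed", "beta"), t = 0.5,
                      c = 1, d = 19) {
  new("PriorSpec", model = match.arg(model), a = a, b = b,
      sigma2Alpha = sigma2Alpha, sigma2_0 = sigma2_0, sigma2_1 = sigma2_1,
      lambda0 = lambda0, piMode = match.arg(piMode), t = t, c = c, d = d)
}

#' Construct an MCMCControl
#'
#' @param nChains number of chains (default 3).
#' @param nBurnin burn-in iterations per chain (default 5000).
#' @param nAdapt adaptation iterations per chain during which slice widths
#'   are tuned (default 5000); discarded with burn-in.
#' @param thin thinning interval (default 3).
#' @param nSavedTotal saved draws pooled across chains (default 9999,
#'   i.e. 3333 per chain under the default 3 chains).
#' @param seed integer seed.
#' @return An [MCMCControl-class] object.
#' @export
mcmcControl <- function(nChains = 3, nBurnin = 5000, nAdapt = 5000, thin = 3,
                        nSavedTotal = 9999, seed = 1) {
  new("MCMCControl", nChains = as.integer(nChains),
      nBurnin = as.integer(nBurnin), nAdapt = as.integer(nAdapt),
      thin = as.integer(thin), nSavedTotal = as.integer(nSavedTotal),
      seed = as.integer(seed))
}

#' Construct a ParameterState
#'
#' @param alpha strictly increasing thresholds (length K-1).
#' @param beta coefficients (length p).
#' @param gamma optional 0/1 inclusion indicators (length p).
#' @param pi optional inclusion probabilities.
#' @param lambda optional positive LASSO rate.
#' @return A [ParameterState-class] object.
#' @export
parameterState <- function(alpha, beta, gamma = numeric(0), pi = numeric(0),
                           lambda = numeric(0)) {
  new("ParameterState", alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), pi = as.numeric(pi),
      lambda = as.numeric(lambda))
}

#' Construct a Bayes-factor test specification
#'
#' @param test "gamma" (point null on the inclusion indicator) or "beta"
#'   (interval null on the coefficient).
#' @param epsilon interval-null half-width (default 0.10).
#' @param bfThreshold rejection threshold, H0 rejected iff BF > threshold
#'   (default 5).
#' @return A [BFTest-class] object.
#' @export
bfTest <- function(test = c("gamma", "beta"), epsilon = 0.10,
                   bfThreshold = 5) {
  new("BFTest", test = match.arg(test), epsilon = epsilon,
      bfThreshold = bfThreshold)
}

# marginal prior inclusion probability E[pi_j]
priorMeanPi <- function(prior) {
  if (prior@piMode == "fixed") prior@t else prior@c / (prior@c + prior@d)
}
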