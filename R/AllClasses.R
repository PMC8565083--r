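#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Ordinal dataset: standardized feature matrix plus ordered response
#'
#' Container for the (X, y) pair entering the cumulative-logit likelihood:
#' an n x p matrix of standardized features (columns mean 0, sample SD 1)
#' and an integer response taking every value in 1..K at least once.
#'
#' @slot X numeric matrix, n samples by p features, standardized columns.
#' @slot y integer vector of length n with values in 1..K.
#' @slot K integer, number of ordered categories (>= 2).
#' @slot featureIds character vector of length p.
#' @slot levels character vector of length K giving the ordered category
#'   labels (lowest first), retained for reporting.
#'
#' @seealso [ordinalDataset()], [standardizeFeatures()]
#' @exportClass OrdinalDataset
setClass("OrdinalDataset",
  representation(X = "matrix", y = "integer", K = "integer",
                 featureIds = "character", levels = "character"))

setValidity("OrdinalDataset", function(object) {
  X <- object@X; y <- object@y; K <- object@K
  if (length(K) != 1L || K < 2L) return("K must be a single integer >= 2")
  if (nrow(X) != length(y)) return("nrow(X) must equal length(y)")
  if (nrow(X) < 1L) return("need at least one sample")
  if (anyNA(X) || anyNA(y)) return("missing values are not allowed")
  if (!all(y %in% seq_len(K))) return("y must take values in 1..K")
  if (!all(seq_len(K) %in% y))
    return(sprintf("every category 1..%d must appear in y at least once", K))
  if (length(object@featureIds) != ncol(X))
    return("featureIds must have one entry per column of X")
  if (length(object@levels) != K)
    return("levels must have length K")
  if (ncol(X) > 0L && nrow(X) > 1L) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8))
      return(paste0("X must be standardized (column means 0, sample SD 1 ",
                    "within 1e-8); see standardizeFeatures()"))
  }
  TRUE
})

#' Prior specification for the four model variants
#'
#' Holds the model variant and all hyperparameters. Defaults are tuned for
#' standardized expression features: a = b = 0.1 for the Gamma(a, b)
#' hyperprior on the LASSO rate lambda, threshold prior variance
#' sigma2Alpha = 10, spike/slab normal variances sigma2_0 = 0.01 and
#' sigma2_1 = 10, and spike rate lambda0 = 20.
#'
#' @slot model character, one of "I", "II", "III", "IV".
#' @slot a,b positive reals, Gamma(a, b) shape and rate for lambda.
#' @slot sigma2Alpha positive real (or length K-1 vector) prior variance of
#'   the thresholds alpha_k.
#' @slot sigma2_0,sigma2_1 spike and slab variances (Model II).
#' @slot lambda0 positive real, spike double-exponential rate (Model III).
#' @slot piMode "fixed" or "beta".
#' @slot t inclusion probability in (0, 1) when piMode = "fixed".
#' @slot c,d positive Beta(c, d) hyperparameters when piMode = "beta".
#'
#' @seealso [priorSpec()]
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(model = "character", a = "numeric", b = "numeric",
                 sigma2Alpha = "numeric", sigma2_0 = "numeric",
                 sigma2_1 = "numeric", lambda0 = "numeric",
                 piMode = "character", t = "numeric",
                 c = "numeric", d = "numeric"))

setValidity("PriorSpec", function(object) {
  if (!object@model %in% c("I", "II", "III", "IV"))
    return("model must be one of 'I', 'II', 'III', 'IV'")
  for (nm in c("a", "b", "sigma2_0", "sigma2_1", "lambda0"))
    if (slot(object, nm) <= 0) return(sprintf("%s must be > 0", nm))
  if (any(object@sigma2Alpha <= 0)) return("sigma2Alpha must be > 0")
  if (object@model == "II" && object@sigma2_0 >= object@sigma2_1)
    return("Model II requires sigma2_0 < sigma2_1 (spike narrower than slab)")
  if (!object@piMode %in% c("fixed", "beta"))
    return("piMode must be 'fixed' or 'beta'")
  if (object@piMode == "fixed" &&
      (object@t <= 0 || object@t >= 1))
    return("t must lie in (0, 1)")
  if (object@piMode == "beta" && (object@c <= 0 || object@d <= 0))
    return("c and d must be > 0")
  TRUE
})

#' MCMC protocol configuration
#'
#' Defaults reproduce the sampling protocol used for the application data:
#' three chains, 5000 burn-in and 5000 adaptation ("tuning") iterations,
#' thinning by 3, and 9999 saved draws in total (split evenly across chains).
#'
#' @slot nChains integer >= 1.
#' @slot nBurnin,nAdapt non-negative integers; adaptation iterations allow
#'   slice-width tuning and are discarded together with burn-in.
#' @slot thin integer >= 1.
#' @slot nSavedTotal integer, saved draws pooled across chains.
#' @slot seed integer seed for all randomness in a fit.
#'
#' @seealso [mcmcControl()]
#' @exportClass MCMCControl
setClass("MCMCControl",
  representation(nChains = "integer", nBurnin = "integer", nAdapt = "integer",
                 thin = "integer", nSavedTotal = "integer", seed = "integer"))

setValidity("MCMCControl", function(object) {
  if (object@nChains < 1L) return("nChains must be >= 1")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@nBurnin < 0L || object@nAdapt < 0L)
    return("nBurnin and nAdapt must be >= 0")
  if (object@nSavedTotal < object@nChains)
    return("nSavedTotal must be at least nChains")
  TRUE
})

#' Parameter state of the cumulative-logit model
#'
#' One point in parameter space: thresholds alpha (strictly increasing),
#' coefficients beta, and, depending on the model variant, inclusion
#' indicators gamma, inclusion probabilities pi, and the LASSO rate lambda.
#'
#' @slot alpha numeric length K-1, strictly increasing.
#' @slot beta numeric length p.
#' @slot gamma numeric length p with values in {0, 1}, or length 0 (Model I).
#' @slot pi numeric, length p or 1 or 0.
#' @slot lambda numeric length 1 or 0.
#'
#' @seealso [parameterState()]
#' @exportClass ParameterState
setClass("ParameterState",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 pi = "numeric", lambda = "numeric"))

setValidity("ParameterState", function(object) {
  a <- object@alpha
  if (length(a) < 1L || anyNA(a)) return("alpha must be non-empty, no NAs")
  if (length(a) > 1L && any(diff(a) <= 0))
    return("alpha must be strictly increasing")
  g <- object@gamma
  if (length(g) && !all(g %in% c(0, 1)))
    return("gamma entries must be 0 or 1")
  if (length(g) && length(g) != length(object@beta))
    return("gamma must match beta in length")
  if (length(object@pi) && any(object@pi <= 0 | object@pi >= 1))
    return("pi entries must lie in (0, 1)")
  if (length(object@lambda) && object@lambda <= 0)
    return("lambda must be > 0")
  TRUE
})

#' Posterior draws from a fitted model
#'
#' Draw arrays are indexed [chain, iteration, parameter]; lambda draws are
#' [chain, iteration]. All stored draws are post burn-in/adaptation and
#' already thinned, so pooling across chains is a simple flatten.
#'
#' @slot model character, model variant.
#' @slot alpha array [chain x iteration x (K-1)].
#' @slot beta array [chain x iteration x p].
#' @slot gamma array of 0/1 draws (Models II-IV) or NULL.
#' @slot pi array (piMode = "beta" only) or NULL.
#' @slot lambda array [chain x iteration] (Models I, III, IV) or NULL.
#' @slot featureIds character length p.
#' @slot prior the [PriorSpec-class] used.
#' @slot control the [MCMCControl-class] used.
#'
#' @exportClass PosteriorSamples
setClass("PosteriorSamples",
  representation(model = "character", alpha = "array", beta = "array",
                 gamma = "arrayOrNULL", pi = "arrayOrNULL",
                 lambda = "arrayOrNULL", featureIds = "character",
                 prior = "PriorSpec", control = "MCMCControl"))

setValidity("PosteriorSamples", function(object) {
  da <- dim(object@alpha)
  if (length(da) != 3L) return("alpha draws must be a 3-d array")
  if (!is.null(object@gamma) && !all(object@gamma %in% c(0, 1)))
    return("gamma draws must be 0/1")
  aa <- object@alpha
  if (da[3L] > 1L) {
    for (k in 2:da[3L])
      if (any(aa[, , k] <= aa[, , k - 1L]))
        return("every stored alpha draw must be strictly increasing")
  }
  TRUE
})

#' Bayes-factor test specification
#'
#' @slot test "gamma" for the point null H0: gamma_j = 0, or "beta" for the
#'   interval null H0: |beta_j| <= epsilon (|gamma_j beta_j| <= epsilon for
#'   Model IV).
#' @slot epsilon positive half-width of the interval null (default 0.10).
#' @slot bfThreshold positive rejection threshold; H0 rejected when
#'   BF > bfThreshold strictly (default 5).
#'
#' @seealso [bfTest()]
#' @exportClass BFTest
setClass("BFTest",
  representation(test = "character", epsilon = "numeric",
                 bfThreshold = "numeric"))

setValidity("BFTest", function(object) {
  if (!object@test %in% c("gamma", "beta"))
    return("test must be 'gamma' or 'beta'")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  if (object@bfThreshold <= 0) return("bfThreshold must be > 0")
  TRUE
})

#' Ground truth of a synthetic dataset
#'
#' @slot betaTrue numeric length p generating coefficient vector.
#' @slot support integer indices of the nonzero coefficients.
#' @slot alphaTrue numeric strictly increasing thresholds.
#' @slot seed integer seed used by the generator.
#'
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(betaTrue = "numeric", support = "integer",
                 alphaTrue = "numeric", seed = "integer"))

setValidity("SimulationTruth", function(object) {
  if (!setequal(object@support, which(object@betaTrue != 0)))
    return("support must index exactly the nonzero entries of betaTrue")
  if (length(object@alphaTrue) > 1L && any(diff(object@alphaTrue) <= 0))
    return("alphaTrue must be strictly increasing")
  TRUE
})
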