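#' Accessors for package classes
#'
#' Standard accessor generics: draw arrays are returned as stored,
#' indexed [chain, iteration, parameter].
#'
#' @param x an object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("responseK", function(x) standardGeneric("responseK"))
#' @rdname accessors
#' @export
setGeneric("alphaDraws", function(x) standardGeneric("alphaDraws"))
#' @rdname accessors
#' @export
setGeneric("betaDraws", function(x) standardGeneric("betaDraws"))
#' @rdname accessors
#' @export
setGeneric("gammaDraws", function(x) standardGeneric("gammaDraws"))
#' @rdname accessors
#' @export
setGeneric("piDraws", function(x) standardGeneric("piDraws"))
#' @rdname accessors
#' @export
setGeneric("lambdaDraws", function(x) standardGeneric("lambdaDraws"))
#' @rdname accessors
#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))

#' @rdname accessors
#' @export
setMethod("featureIds", "OrdinalDataset", function(x) x@featureIds)
#' @rdname accessors
#' @export
setMethod("featureIds", "PosteriorSamples", function(x) x@featureIds)
#' @rdname accessors
#' @export
setMethod("responseK", "OrdinalDataset", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("alphaDraws", "PosteriorSamples", function(x) x@alpha)
#' @rdname accessors
#' @export
setMethod("betaDraws", "PosteriorSamples", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("gammaDraws", "PosteriorSamples", function(x) x@gamma)
#' @rdname accessors
#' @export
setMethod("piDraws", "PosteriorSamples", function(x) x@pi)
#' @rdname accessors
#' @export
setMethod("lambdaDraws", "PosteriorSamples", function(x) x@lambda)
#' @rdname accessors
#' @export
setMethod("modelVariant", "PosteriorSamples", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("modelVariant", "PriorSpec", function(x) x@model)

#' Pool draws of one scalar parameter across chains
#'
#' Flattens the [chain, iteration] draws of a single feature's beta_j,
#' gamma_j, gamma_j * beta_j, a threshold alpha_k, or lambda into one
#' vector. All stored draws are post burn-in, so pooling is a flatten.
#'
#' @param samples a [PosteriorSamples-class] object.
#' @param param one of "beta", "gamma", "gammabeta", "alpha", "lambda", "pi".
#' @param index feature index/id (for beta, gamma, gammabeta, pi) or
#'   threshold index k (for alpha); ignored for lambda.
#' @return numeric vector of pooled draws.
#' @export
pooledDraws <- function(samples, param = c("beta", "gamma", "gammabeta",
                                           "alpha", "lambda", "pi"),
                        index = 1L) {
  param <- match.arg(param)
  j <- resolveFeature(samples, index, param)
  switch(param,
    beta = as.vector(samples@beta[, , j]),
    gamma = {
      if (is.null(samples@gamma)) stop("no gamma draws for Model I")
      as.vector(samples@gamma[, , j])
    },
    gammabeta = {
      if (is.null(samples@gamma)) stop("no gamma draws for Model I")
      as.vector(samples@gamma[, , j] * samples@beta[, , j])
    },
    alpha = as.vector(samples@alpha[, , index]),
    lambda = {
      if (is.null(samples@lambda)) stop("no lambda draws for Model II")
      as.vector(samples@lambda)
    },
    pi = {
      if (is.null(samples@pi)) stop("pi draws only stored under piMode='beta'")
      as.vector(samples@pi[, , j])
    })
}

resolveFeature <- function(samples, index, param) {
  if (param %in% c("alpha", "lambda")) return(index)
  if (is.character(index)) {
    j <- match(index, samples@featureIds)
    if (is.na(j)) stop("unknown feature id: ", index)
    j
  } else as.integer(index)
}

setMethod("show", "OrdinalDataset", function(object) {
  cat("OrdinalDataset:", nrow(object@X), "samples x", ncol(object@X),
      "features,", object@K, "ordered categories\n")
  tab <- table(factor(object@y, levels = seq_len(object@K),
                      labels = object@levels))
  cat("  category counts:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec: Model", object@model, "\n")
  cat(sprintf("  lambda ~ Gamma(a=%g, b=%g); sigma2Alpha=%s\n", object@a,
              object@b, paste(object@sigma2Alpha, collapse = ",")))
  if (object@model == "II")
    cat(sprintf("  spike/slab normal: sigma2_0=%g, sigma2_1=%g\n",
                object@sigma2_0, object@sigma2_1))
  if (object@model == "III")
    cat(sprintf("  spike DE rate lambda0=%g\n", object@lambda0))
  if (object@model != "I")
    cat("  pi:", if (object@piMode == "fixed")
      sprintf("fixed t=%g", object@t) else
      sprintf("Beta(%g, %g)", object@c, object@d), "\n")
})

setMethod("show", "PosteriorSamples", function(object) {
  d <- dim(object@beta)
  cat("PosteriorSamples: Model", object@model, "-", d[1], "chain(s) x",
      d[2], "saved iterations,", d[3], "features,",
      dim(object@alpha)[3], "threshold(s)\n")
})

setMethod("show", "MCMCControl", function(object) {
  cat(sprintf(
    "MCMCControl: %d chains, burn-in %d, adapt %d, thin %d, %d saved total, seed %d\n",
    object@nChains, object@nBurnin, object@nAdapt, object@thin,
    object@nSavedTotal, object@seed))
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", length(object@betaTrue), "features,",
      length(object@support), "in support; seed", object@seed, "\n")
})
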