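#' Simulate a high-dimensional ordinal dataset with known sparse truth
#'
#' Generates features and response through the same latent-logistic
#' mechanism the models assume: Z_i = beta' x_i + logistic(0, 1) noise, and
#' Y_i = k when alpha_{k-1} < Z_i <= alpha_k. Features are mean-zero
#' unit-variance Gaussians with exchangeable pairwise correlation `rho`
#' (then standardized); the coefficient vector has `supportSize` entries of
#' magnitude `effect` with alternating signs (both directions of
#' association, as in real expression data), the rest zero.
#'
#' If a category is missing from the generated response the logistic noise
#' is redrawn (seed-forward, logged via message) up to 50 times.
#'
#' @param n number of samples.
#' @param p number of features.
#' @param K number of ordered categories.
#' @param supportSize number of nonzero coefficients (<= p).
#' @param effect absolute effect size of nonzero coefficients.
#' @param alpha thresholds, length K-1 strictly increasing. Default for
#'   K = 3 reproduces a 97:259:97 category composition
#'   (favorable:intermediate:adverse); otherwise equal-probability cuts.
#' @param rho exchangeable feature correlation in [0, 1).
#' @param seed integer seed; same seed, same dataset.
#' @return list with `data` (an [OrdinalDataset-class]) and `truth`
#'   (a [SimulationTruth-class]).
#' @examples
#' sim <- simulateOrdinal(n = 100, p = 10, supportSize = 2, effect = 1.5,
#'                        seed = 7)
#' table(sim$data@y)
#' @export
simulateOrdinal <- function(n, p, K = 3, supportSize = 0, effect = 1,
                            alpha = NULL, rho = 0, seed = 1) {
  stopifnot(n >= K, p >= 0, K >= 2, supportSize <= p, rho >= 0, rho < 1)
  if (is.null(alpha)) {
    alpha <- if (K == 3) stats::qlogis(cumsum(c(97, 259) / 446))
             else stats::qlogis(seq_len(K - 1) / K)
  }
  if (length(alpha) != K - 1 || (K > 2 && any(diff(alpha) <= 0)))
    stop("alpha must be strictly increasing with length K-1")
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0 && p > 0) {
    z0 <- stats::rnorm(n)
    X <- sqrt(rho) * z0 + sqrt(1 - rho) * X
  }
  if (p > 0) X <- standardizeFeatures(X)
  colnames(X) <- if (p) sprintf("feat%03d", seq_len(p)) else NULL
  beta <- numeric(p)
  if (supportSize > 0)
    beta[seq_len(supportSize)] <- effect * (-1)^(seq_len(supportSize) - 1)
  etaLin <- if (p) as.vector(X %*% beta) else numeric(n)
  y <- NULL
  for (try in seq_len(50L)) {
    Z <- etaLin + stats::rlogis(n)
    yTry <- 1L + as.integer(rowSums(outer(Z, alpha, `>`)))
    if (all(seq_len(K) %in% yTry)) { y <- yTry; break }
    message("simulateOrdinal: category missing, redrawing noise (attempt ",
            try, ")")
  }
  if (is.null(y))
    stop("could not cover all ", K, " categories after 50 noise redraws")
  data <- ordinalDataset(X, y, levels = as.character(seq_len(K)))
  truth <- new("SimulationTruth", betaTrue = beta,
               support = which(beta != 0), alphaTrue = as.numeric(alpha),
               seed = as.integer(seed))
  list(data = data, truth = truth)
}

#' Score a selected feature set against the generating truth
#'
#' Sensitivity is |selected intersect support| / |support|; the false
#' discovery rate is |selected \ support| / max(|selected|, 1), so an empty
#' selection scores FDR 0.
#'
#' @param selected selected features: integer indices, or feature ids
#'   matching `featureIds`.
#' @param truth a [SimulationTruth-class] with non-empty support.
#' @param featureIds optional id vector for resolving character `selected`.
#' @return list with `sensitivity`, `fdr`, `n_selected`.
#' @examples
#' tr <- new("SimulationTruth", betaTrue = c(1, -1, 0), support = c(1L, 2L),
#'           alphaTrue = 0, seed = 1L)
#' scoreSelection(c(2, 3), tr)
#' @export
scoreSelection <- function(selected, truth, featureIds = NULL) {
  stopifnot(is(truth, "SimulationTruth"))
  if (!length(truth@support))
    stop("sensitivity undefined: the generating support is empty")
  if (is.character(selected)) {
    if (is.null(featureIds))
      stop("character 'selected' requires featureIds")
    selected <- match(selected, featureIds)
    if (anyNA(selected)) stop("unknown feature id in 'selected'")
  }
  selected <- unique(as.integer(selected))
  if (length(selected) && (min(selected) < 1 ||
      max(selected) > length(truth@betaTrue)))
    stop("selected indices out of range")
  tp <- length(intersect(selected, truth@support))
  list(sensitivity = tp / length(truth@support),
       fdr = (length(selected) - tp) / max(length(selected), 1L),
       n_selected = length(selected))
}
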