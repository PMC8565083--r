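#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split, non-rank-normalized) R-hat: with m chains of n
#' draws, W the mean within-chain variance and B = n * var(chain means),
#' returns sqrt(((n - 1)/n * W + B/n) / W). Values slightly below 1 are
#' possible for finite n and are reported as computed. A `split = TRUE`
#' variant halves each chain first.
#'
#' When every chain has zero variance: returns 1 if all chain means agree
#' (a degenerately converged parameter), Inf otherwise.
#'
#' @param chainDraws numeric matrix, chains in rows, iterations in columns
#'   (>= 2 chains, >= 10 iterations).
#' @param split compute the split-chain variant (default FALSE).
#' @return the scalar PSRF.
#' @examples
#' psrf(rbind(rnorm(1000), rnorm(1000)))
#' @export
psrf <- function(chainDraws, split = FALSE) {
  x <- as.matrix(chainDraws)
  if (nrow(x) < 2L) stop("need at least 2 chains")
  if (split) {
    half <- ncol(x) %/% 2L
    x <- rbind(x[, seq_len(half), drop = FALSE],
               x[, half + seq_len(half), drop = FALSE])
  }
  n <- ncol(x)
  if (n < 10L) stop("need at least 10 iterations per chain")
  W <- mean(apply(x, 1L, stats::var))
  means <- rowMeans(x)
  Bn <- stats::var(means)              # B/n
  if (W == 0) return(if (Bn == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Convergence report for a fitted model
#'
#' Computes the PSRF for every threshold alpha_k, for lambda when present,
#' and for each monitored coefficient beta_j (default: all). Binary gamma
#' chains are excluded from R-hat (ill-behaved for indicators); their
#' per-chain posterior means are reported instead.
#'
#' @param samples a [PosteriorSamples-class] with >= 2 chains.
#' @param cutoff flag parameters with PSRF above this value (default 1.1).
#' @param monitor feature ids/indices whose beta chains to monitor
#'   (default all).
#' @param split use split-chain PSRF (default FALSE).
#' @return a `ConvergenceReport` list: `psrf` (named numeric), `flagged`
#'   (character), `cutoff`, `n_chains`, `n_iter`, and `gamma_chain_means`
#'   (matrix chains x features, or NULL).
#' @export
convergenceReport <- function(samples, cutoff = 1.1, monitor = NULL,
                              split = FALSE) {
  stopifnot(is(samples, "PosteriorSamples"))
  Km1 <- dim(samples@alpha)[3L]
  p <- dim(samples@beta)[3L]
  vals <- c()
  for (k in seq_len(Km1))
    vals[paste0("alpha", k)] <- psrf(samples@alpha[, , k], split)
  if (!is.null(samples@lambda))
    vals["lambda"] <- psrf(samples@lambda, split)
  idx <- if (is.null(monitor)) seq_len(p) else
    vapply(monitor, resolveFeature, numeric(1), samples = samples,
           param = "beta")
  for (j in idx)
    vals[samples@featureIds[j]] <- psrf(samples@beta[, , j], split)
  gm <- NULL
  if (!is.null(samples@gamma)) {
    gm <- apply(samples@gamma, c(1L, 3L), mean)
    colnames(gm) <- samples@featureIds
  }
  structure(
    list(psrf = vals, flagged = names(vals)[vals > cutoff], cutoff = cutoff,
         n_chains = dim(samples@beta)[1L], n_iter = dim(samples@beta)[2L],
         gamma_chain_means = gm),
    class = "ConvergenceReport")
}

#' @export
print.ConvergenceReport <- function(x, ...) {
  cat(sprintf("ConvergenceReport: %d chains x %d iterations, cutoff %.3g\n",
              x$n_chains, x$n_iter, x$cutoff))
  cat(sprintf("  max PSRF %.4f (%s)\n", max(x$psrf),
              names(x$psrf)[which.max(x$psrf)]))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  else cat("  no parameters above the cutoff\n")
  invisible(x)
}
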