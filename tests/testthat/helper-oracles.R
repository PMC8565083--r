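# Independent oracles used by the tests. Everything here is deliberately
# written from first principles (closed-form prior algebra, dense-grid
# numerical integration, direct Monte-Carlo prior sampling) so that it
# shares no code path with the package's samplers.

# ---- Monte-Carlo standard errors ------------------------------------------

# effective sample size per chain (coda's spectral estimator), summed
essTotal <- function(chainMat) {
  sum(apply(as.matrix(chainMat), 1L, function(x) coda::effectiveSize(x)))
}

# MC standard error of the pooled posterior mean
mcseMean <- function(chainMat) {
  stats::sd(as.vector(chainMat)) / sqrt(max(essTotal(chainMat), 4))
}

# MC standard error of the pooled posterior SD (normal approximation)
mcseSd <- function(chainMat) {
  stats::sd(as.vector(chainMat)) / sqrt(2 * max(essTotal(chainMat), 4))
}

# ---- prior samplers (for Monte-Carlo prior checks and Geweke runs) --------

# ordered product-normal prior on thresholds: with a shared variance the
# ordering-constrained product normal is the sorted iid draw
rPriorAlpha <- function(Km1, sigma2Alpha) sort(rnorm(Km1, 0, sqrt(sigma2Alpha)))

rDE <- function(n, rate) ifelse(runif(n) < 0.5, -1, 1) * rexp(n, rate)

# one draw of the full parameter state from the prior of a given variant
rPriorState <- function(prior, p, Km1) {
  st <- list(alpha = rPriorAlpha(Km1, prior@sigma2Alpha[1L]))
  pibar <- if (prior@piMode == "fixed") prior@t else
    rbeta(p, prior@c, prior@d)
  model <- prior@model
  if (model %in% c("I", "IV")) {
    lam <- rgamma(1, prior@a, prior@b)
    st$lambda <- lam
    st$beta <- rDE(p, lam)
  } else if (model == "II") {
    st$beta <- numeric(p)
  } else {
    lam <- rgamma(1, prior@a, prior@b)
    st$lambda <- lam
  }
  if (model != "I") {
    st$gamma <- rbinom(p, 1, pibar)
    if (prior@piMode == "beta") st$pi <- pibar
    if (model == "II")
      st$beta <- rnorm(p, 0, sqrt(ifelse(st$gamma == 1, prior@sigma2_1,
                                         prior@sigma2_0)))
    if (model == "III")
      st$beta <- rDE(p, ifelse(st$gamma == 1, st$lambda, prior@lambda0))
  }
  st
}

# simulate a response from the cumulative-logit model at a given state
rResponse <- function(state, X, model) {
  coef <- if (model == "IV") state$gamma * state$beta else state$beta
  eta <- as.vector(X %*% coef)
  u <- runif(nrow(X))
  y <- rep(1L, nrow(X))
  for (a in state$alpha) y <- y + as.integer(u > plogis(a - eta))
  y
}

# ---- dense-grid posterior oracle (n small, p = 2, K = 3) ------------------

# log joint DE-Gamma marginal of m coefficients with |beta| sum S:
# integral over lambda ~ Gamma(a, b) of prod (lambda/2) e^{-lambda |b_j|}
logDEGammaJoint <- function(S, m, a, b) {
  -m * log(2) + a * log(b) + lgamma(a + m) - lgamma(a) -
    (a + m) * log(b + S)
}

# Marginal posterior moments by brute-force integration on a dense grid.
# Returns means/SDs for alpha1, alpha2, beta1, beta2; for Model IV also
# E[gamma_j] and moments of gamma_j * beta_j (mixing over the four
# indicator configurations, with excluded coefficients integrated out
# analytically).
# default coefficient grid: sinh-spaced so that the near-zero spike of the
# heavy-tailed priors (scale ~0.05) and the far tails (to ~|8|) are both
# resolved; bLogJac carries log of the per-atom spacing so that indicator
# configurations of different dimension (Model IV) are weighted on a
# common measure
sinhGrid <- function(nU = 121, scale = 0.05, bMax = 8) {
  uMax <- asinh(bMax / scale)
  u <- seq(-uMax, uMax, length.out = nU)
  du <- u[2L] - u[1L]
  list(b = scale * sinh(u), logJac = log(scale * cosh(u) * du))
}

gridPosteriorOracle <- function(X, y, prior,
                                aGrid = seq(-6, 6, length.out = 61),
                                bGrid = NULL, bLogJac = NULL) {
  if (is.null(bGrid)) {
    sg <- sinhGrid()
    bGrid <- sg$b
    bLogJac <- sg$logJac
  }
  if (is.null(bLogJac)) bLogJac <- rep(0, length(bGrid))
  model <- prior@model
  stopifnot(ncol(X) == 2L, max(y) == 3L)
  pibar <- if (prior@piMode == "fixed") prior@t else
    prior@c / (prior@c + prior@d)
  s2a <- prior@sigma2Alpha[1L]
  idx1 <- y == 1L; idx2 <- y == 2L; idx3 <- y == 3L
  na <- length(aGrid)

  # accumulators over everything: log-weights handled pair-block-wise
  stats <- c("a1", "a1sq", "a2", "a2sq", "b1", "b1sq", "b2", "b2sq",
             "g1", "g2", "gb1", "gb1sq", "gb2", "gb2sq")
  blockMax <- list(); blockSums <- list()

  accumulate <- function(lp, vals) {
    # lp: log posterior over a vector of grid atoms; vals: named list of
    # statistic vectors conformable with lp
    m <- max(lp)
    if (!is.finite(m)) return(invisible())
    w <- exp(lp - m)
    s <- vapply(stats, function(nm) {
      v <- vals[[nm]]; if (is.null(v)) 0 else sum(w * v)
    }, numeric(1))
    blockMax[[length(blockMax) + 1L]] <<- m
    blockSums[[length(blockSums) + 1L]] <<- c(w0 = sum(w), s)
  }

  # per-config computation; gamma = c(g1, g2) (Models I-III use c(1,1) with
  # the variant's own beta prior; the config weight handles pi for IV)
  runConfig <- function(gcfg, logwcfg, logPriorPair, logPriorSingle) {
    act <- which(gcfg == 1L)  # coefficients present in the predictor
    if (length(act) == 2L) {
      bp <- as.matrix(expand.grid(b1 = bGrid, b2 = bGrid))
      jp <- as.matrix(expand.grid(j1 = bLogJac, j2 = bLogJac))
      eta <- X %*% t(bp)                       # n x nb
      lpb <- logPriorPair(bp[, 1L], bp[, 2L]) + jp[, 1L] + jp[, 2L]
      vals <- list(b1 = bp[, 1L], b1sq = bp[, 1L]^2,
                   b2 = bp[, 2L], b2sq = bp[, 2L]^2,
                   g1 = 1, g2 = 1,
                   gb1 = bp[, 1L], gb1sq = bp[, 1L]^2,
                   gb2 = bp[, 2L], gb2sq = bp[, 2L]^2)
    } else if (length(act) == 1L) {
      bp <- matrix(bGrid, ncol = 1L)
      eta <- X[, act, drop = FALSE] %*% t(bp)  # n x nb
      lpb <- logPriorSingle(bp[, 1L]) + bLogJac
      vals <- list(g1 = gcfg[1L], g2 = gcfg[2L])
      if (act == 1L) {
        vals$b1 <- bp[, 1L]; vals$b1sq <- bp[, 1L]^2
        vals$gb1 <- bp[, 1L]; vals$gb1sq <- bp[, 1L]^2
      } else {
        vals$b2 <- bp[, 1L]; vals$b2sq <- bp[, 1L]^2
        vals$gb2 <- bp[, 1L]; vals$gb2sq <- bp[, 1L]^2
      }
    } else {
      eta <- matrix(0, nrow(X), 1L)
      lpb <- 0
      vals <- list(g1 = gcfg[1L], g2 = gcfg[2L])
    }
    nb <- ncol(eta)
    # threshold-dependent pieces
    S1 <- matrix(vapply(aGrid, function(a)
      colSums(log(plogis(a - eta[idx1, , drop = FALSE]))), numeric(nb)),
      nrow = nb)
    S3 <- matrix(vapply(aGrid, function(a)
      colSums(log(plogis(eta[idx3, , drop = FALSE] - a))), numeric(nb)),
      nrow = nb)
    # S1, S3: nb x na
    n2 <- sum(idx2)
    Q <- array(0, c(na, nb, n2))  # plogis(a - eta_i) for mid-category obs
    etaMid <- eta[idx2, , drop = FALSE]
    for (ai in seq_len(na))
      Q[ai, , ] <- t(plogis(aGrid[ai] - etaMid))
    lpa <- dnorm(aGrid, 0, sqrt(s2a), log = TRUE)
    pairLp <- function(i1, i2, cols) {
      M <- Q[i2, cols, , drop = FALSE] - Q[i1, cols, , drop = FALSE]
      dim(M) <- c(length(cols), n2)
      S2 <- rowSums(log(pmax(M, 1e-300)))
      logwcfg + lpa[i1] + lpa[i2] + lpb[cols] + S1[cols, i1] + S2 +
        S3[cols, i2]
    }
    # coarse pass over a beta subgrid locates the (alpha1, alpha2) pairs
    # carrying posterior mass; pairs >25 nats below the maximum are skipped
    coarse <- unique(round(seq(1L, nb, length.out = min(nb, 400L))))
    pairs <- which(upper.tri(matrix(0, na, na)), arr.ind = TRUE)
    pm <- apply(pairs, 1L, function(ii)
      max(pairLp(ii[1L], ii[2L], coarse)))
    keep <- pm > max(pm) - 25
    for (r in which(keep)) {
      i1 <- pairs[r, 1L]; i2 <- pairs[r, 2L]
      lp <- pairLp(i1, i2, seq_len(nb))
      accumulate(lp, c(vals, list(a1 = rep(aGrid[i1], nb),
                                  a1sq = rep(aGrid[i1]^2, nb),
                                  a2 = rep(aGrid[i2], nb),
                                  a2sq = rep(aGrid[i2]^2, nb))))
    }
  }

  a <- prior@a; b <- prior@b
  if (model == "I") {
    runConfig(c(1L, 1L), 0,
              function(b1, b2) logDEGammaJoint(abs(b1) + abs(b2), 2, a, b),
              NULL)
  } else if (model == "II") {
    mixLd <- function(v) log((1 - pibar) * dnorm(v, 0, sqrt(prior@sigma2_0)) +
                             pibar * dnorm(v, 0, sqrt(prior@sigma2_1)))
    runConfig(c(1L, 1L), 0, function(b1, b2) mixLd(b1) + mixLd(b2), NULL)
  } else if (model == "III") {
    lam0 <- prior@lambda0
    spikeLd <- function(v) log(lam0 / 2) - lam0 * abs(v)
    pairLd <- function(b1, b2) {
      # sum over the four indicator configurations (slab coords share lambda)
      l00 <- spikeLd(b1) + spikeLd(b2) + 2 * log(1 - pibar)
      l10 <- logDEGammaJoint(abs(b1), 1, a, b) + spikeLd(b2) +
        log(pibar) + log(1 - pibar)
      l01 <- spikeLd(b1) + logDEGammaJoint(abs(b2), 1, a, b) +
        log(pibar) + log(1 - pibar)
      l11 <- logDEGammaJoint(abs(b1) + abs(b2), 2, a, b) + 2 * log(pibar)
      m <- pmax(l00, l10, l01, l11)
      m + log(exp(l00 - m) + exp(l10 - m) + exp(l01 - m) + exp(l11 - m))
    }
    runConfig(c(1L, 1L), 0, pairLd, NULL)
  } else {  # Model IV: four predictor configurations
    pairLd <- function(b1, b2) logDEGammaJoint(abs(b1) + abs(b2), 2, a, b)
    singleLd <- function(v) logDEGammaJoint(abs(v), 1, a, b)
    for (g1 in 0:1) for (g2 in 0:1) {
      lw <- (g1 + g2) * log(pibar) + (2 - g1 - g2) * log(1 - pibar)
      runConfig(c(g1, g2), lw, pairLd, singleLd)
    }
  }

  M <- max(unlist(blockMax))
  tot <- Reduce(`+`, Map(function(m, s) exp(m - M) * s, blockMax, blockSums))
  z <- tot[["w0"]]
  mom <- tot[-1L] / z
  out <- list(
    mean = c(alpha1 = mom[["a1"]], alpha2 = mom[["a2"]],
             beta1 = mom[["b1"]], beta2 = mom[["b2"]],
             gamma1 = mom[["g1"]], gamma2 = mom[["g2"]],
             gammabeta1 = mom[["gb1"]], gammabeta2 = mom[["gb2"]]),
    sd = c(alpha1 = sqrt(max(mom[["a1sq"]] - mom[["a1"]]^2, 0)),
           alpha2 = sqrt(max(mom[["a2sq"]] - mom[["a2"]]^2, 0)),
           beta1 = sqrt(max(mom[["b1sq"]] - mom[["b1"]]^2, 0)),
           beta2 = sqrt(max(mom[["b2sq"]] - mom[["b2"]]^2, 0)),
           gammabeta1 = sqrt(max(mom[["gb1sq"]] - mom[["gb1"]]^2, 0)),
           gammabeta2 = sqrt(max(mom[["gb2sq"]] - mom[["gb2"]]^2, 0))))
  out
}
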