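# small fixture builders shared across test files

# deterministic tiny dataset with all three categories present
tinyData <- function(n = 15, p = 2, seed = 11) {
  sim <- simulateOrdinal(n = n, p = p, K = 3, supportSize = min(1, p),
                         effect = 1, seed = seed)
  sim$data
}

# hand-assemble a PosteriorSamples object with given pooled draws; draws are
# split over 2 chains so pooling semantics are exercised
fakeSamples <- function(beta, gamma = NULL, model = if (is.null(gamma)) "I" else "IV",
                        prior = priorSpec(model, t = 0.5)) {
  beta <- as.matrix(beta)          # iterations x p
  N <- nrow(beta); p <- ncol(beta)
  stopifnot(N %% 2 == 0)
  half <- N / 2
  toArr <- function(m) {
    a <- array(0, c(2, half, ncol(m)))
    a[1, , ] <- m[seq_len(half), , drop = FALSE]
    a[2, , ] <- m[half + seq_len(half), , drop = FALSE]
    a
  }
  alpha <- toArr(matrix(rep(c(-1, 1), each = N), N, 2))
  new("PosteriorSamples", model = model, alpha = alpha, beta = toArr(beta),
      gamma = if (is.null(gamma)) NULL else toArr(as.matrix(gamma)),
      pi = NULL,
      lambda = if (model %in% c("I", "III", "IV"))
        array(1, c(2, half)) else NULL,
      featureIds = paste0("f", seq_len(p)),
      prior = prior,
      control = mcmcControl(nChains = 2, nBurnin = 0, nAdapt = 0, thin = 1,
                            nSavedTotal = N))
}
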