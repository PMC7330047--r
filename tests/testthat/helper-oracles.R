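# Independent brute-force oracles and tiny-instance builders used across the
# suite. These deliberately avoid the package's computational shortcuts
# (recurrences, caching, log-sum-exp) so they can certify them.

# zero-observation probability by direct summation to a very high quantile
bruteZeroObsLogProb <- function(mu, phi, g0, g1) {
  xmax <- max(200, qnbinom(1 - 1e-15, size = phi, mu = mu) + 50)
  xs <- seq_len(xmax)
  log(dnbinom(0, size = phi, mu = mu) +
        sum(plogis(g0 + g1 * xs) * dnbinom(xs, size = phi, mu = mu)))
}

# observed-data log likelihood by naive mixture enumeration (no log-sum-exp)
bruteObservedLogLik <- function(y, batch, pars, nzf = FALSE) {
  G <- nrow(y); N <- ncol(y); K <- ncol(pars$beta)
  total <- 0
  for (i in seq_len(N)) {
    b <- batch[i]
    cellsum <- 0
    for (k in seq_len(K)) {
      lp <- log(pars$pi[b, k])
      for (g in seq_len(G)) {
        mu <- exp(pars$alpha[g] + pars$beta[g, k] + pars$nu[g, b] +
                    pars$delta[i])
        ph <- pars$phi[g, b]
        lp <- lp + if (nzf) {
          dnbinom(y[g, i], size = ph, mu = mu, log = TRUE)
        } else if (y[g, i] == 0) {
          bruteZeroObsLogProb(mu, ph, pars$gamma0[b], pars$gamma1[b])
        } else {
          dnbinom(y[g, i], size = ph, mu = mu, log = TRUE) +
            log(1 - plogis(pars$gamma0[b] + pars$gamma1[b] * y[g, i]))
        }
      }
      cellsum <- cellsum + exp(lp)
    }
    total <- total + log(cellsum)
  }
  total
}

# a small consistent model state for conditional-density oracle tests
makeTinyState <- function(G = 3, N = 4, B = 2, K = 2, seed = 42) {
  set.seed(seed)
  batch <- rep(seq_len(B), length.out = N)
  W <- rep(seq_len(K), length.out = N)
  pars <- list(
    alpha = rnorm(G, 1, 0.5),
    beta = cbind(0, matrix(rnorm(G * (K - 1), 0, 1), G, K - 1)),
    nu = cbind(0, matrix(rnorm(G * (B - 1), 0, 0.5), G, B - 1)),
    delta = ifelse(duplicated(batch), rnorm(N, 0, 0.3), 0),
    phi = matrix(runif(G * B, 1, 5), G, B),
    gamma0 = rnorm(B, 0, 0.3),
    gamma1 = -runif(B, 0.05, 0.3),
    pi = matrix(1 / K, B, K))
  mu <- exp(pars$alpha + pars$beta[, W] + pars$nu[, batch] +
              rep(pars$delta, each = G))
  X <- matrix(rnbinom(G * N, size = pars$phi[, batch], mu = mu), G, N)
  Z <- matrix(0L, G, N)
  pos <- which(X > 0)
  Z[pos] <- rbinom(length(pos), 1,
                   plogis(rep(pars$gamma0[batch], each = G)[pos] +
                            rep(pars$gamma1[batch], each = G)[pos] * X[pos]))
  Y <- X * (1L - Z)
  L <- matrix(0L, G, K)
  list(Y = Y, X = X, Z = Z, W = W, batch = batch, pars = pars, L = L,
       G = G, N = N, B = B, K = K)
}

# simulate a small well-separated dataset for recovery-style checks
quickSim <- function(B = 2, K = 3, nPerBatch = c(60, 60), G = 80, nDE = 20,
                     seed = 3, pi = NULL) {
  d <- buildDesign("chain_type", B = B, K = K, nPerBatch = nPerBatch, pi = pi)
  tr <- simulateTruth(d, simConfig(nGenes = G, nDE = nDE), seed = seed)
  simulateData(tr, seed = seed + 1)
}

# uniform compositions over the present types of a design family
uniformChainPi <- function(B, K) {
  pr <- scBatchMix:::.chainPresence(B, K)
  pr / rowSums(pr)
}

# assemble a MixChains object from explicit draw arrays (for summarization
# and diagnostic tests that need exactly controlled posterior samples)
fakeChains <- function(y, batch, K, chains) {
  G <- nrow(y); N <- ncol(y); B <- max(batch)
  chains <- lapply(chains, function(ch) {
    T <- dim(ch$alpha)[2]
    defaults <- list(
      alpha = matrix(0, G, T), beta = array(0, c(G, K, T)),
      nu = array(0, c(G, B, T)), delta = matrix(0, N, T),
      phi = array(4, c(G, B, T)), gamma0 = matrix(0, B, T),
      gamma1 = matrix(-0.1, B, T), pi = array(1 / K, c(B, K, T)),
      W = matrix(0L, N, T), L = array(0L, c(G, K, T)),
      p = rep(0.5, T), tau0sq = rep(0.01, T),
      sumXZ1 = matrix(0, G, N), cntZ1 = matrix(0L, G, N),
      finalX = y, finalZ = matrix(0L, G, N),
      acceptance = list(alpha = 0.3), nStored = T)
    utils::modifyList(defaults, ch)
  })
  new("MixChains", chains = chains, counts = y, batch = as.integer(batch),
      K = as.integer(K), nIter = 2L * chains[[1]]$nStored,
      burnin = chains[[1]]$nStored, thin = 1L, seed = 1L,
      variant = "full", hyper = mixHyper())
}

y2bc <- function(y, batch = rep(1, ncol(y))) BatchCounts(y, batch = batch)
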