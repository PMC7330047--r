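# Metropolis-within-Gibbs fitting: hyperparameters, initialization, and the
# multi-chain driver around the compiled sampler.

#' Hyperparameters of the prior
#'
#' Weakly informative defaults: flat-ish normal priors (variance 100) on the
#' log-scale effects, Dirichlet(1) on compositions, Exp(1) on the negated
#' dropout slope, Gamma(1, 0.1) on overdispersions (prior mean 10),
#' Beta(1, 3) on the slab probability, and an inverse-gamma spike variance
#' with small prior mean (0.01) against a large fixed slab variance (100).
#' All values can be overridden and are recorded in the fit.
#'
#' @param ... named overrides of any default listed above.
#' @return named list of hyperparameters.
#' @export
mixHyper <- function(...) {
  h <- list(xi = 1, sigma_z0_sq = 100, a_gamma = 1, b_gamma = 1,
            m_a = 0, sigma_a_sq = 100, m_c = 0, sigma_c_sq = 100,
            m_d = 0, sigma_d_sq = 100, kappa_phi = 1, tau_phi = 0.1,
            a_p = 1, b_p = 3, a_tau = 2, b_tau = 0.01, tau_beta1_sq = 100)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(h))
    if (length(bad)) stop("unknown hyperparameters: ", paste(bad, collapse = ", "))
    h <- modifyList(h, dots)
  }
  if (any(unlist(h[c("xi", "sigma_z0_sq", "a_gamma", "b_gamma", "sigma_a_sq",
                     "sigma_c_sq", "sigma_d_sq", "kappa_phi", "tau_phi",
                     "a_p", "b_p", "a_tau", "b_tau", "tau_beta1_sq")]) <= 0))
    stop("variance/shape/rate hyperparameters must be positive")
  h
}

#' Initialize the sampler state
#'
#' Cell types start from k-means (K clusters) on log1p library-size-scaled
#' counts; the baseline from per-gene log means of nonzero counts; cell-type
#' and batch effects from empirical cluster/batch log-mean contrasts
#' (thresholded, so the spike-and-slab state starts sparse); size factors
#' by median-of-ratios against the (batch, cluster) mean profile, anchored
#' at each batch's first cell;
#' overdispersions by per-(batch, gene) method of moments floored at 0.1.
#' Zero entries are provisionally marked as dropouts with probability one
#' half, with the underlying count drawn from a shifted negative binomial.
#' Deterministic given the RNG state.
#'
#' @param data a \linkS4class{BatchCounts}.
#' @param K number of cell types to fit.
#' @param hyper list from \code{\link{mixHyper}}.
#' @param variant "full" or "nzf" (the latter fixes Z = 0, X = Y).
#' @param nStarts number of single-start k-means candidate partitions
#'   scored (in addition to one multi-start run).
#' @return named list of initial values (R-side conventions, W in 1..K).
#' @export
initializeChain <- function(data, K, hyper = mixHyper(),
                            variant = c("full", "nzf"), nStarts = 12) {
  variant <- match.arg(variant)
  cand <- .initCandidates(data, K, nStarts)
  .buildInit(data, K, hyper, variant, cand[[1]])
}

# Common per-gene dispersion for partition scoring, by method of moments
# within the groups of the finest available partition crossed with batch
# (the least-fused grouping, so fusion misfit is not absorbed into phi).
.estimatePhiG <- function(y, b, clFine) {
  G <- nrow(y)
  grp <- interaction(clFine, b, drop = TRUE)
  phis <- matrix(NA_real_, G, nlevels(grp))
  for (j in seq_len(nlevels(grp))) {
    idx <- which(grp == levels(grp)[j])
    if (length(idx) < 5) next
    m <- rowMeans(y[, idx, drop = FALSE])
    v <- apply(y[, idx, drop = FALSE], 1, var)
    phis[, j] <- ifelse(v > m & m > 0, m^2 / (v - m), 50)
  }
  ph <- apply(phis, 1, median, na.rm = TRUE)
  ph[!is.finite(ph)] <- 3
  pmin(pmax(ph, 0.5), 50)
}

# Label-invariant model-based score of a candidate partition: a short
# Poisson backfit alternating shared per-gene batch multipliers (the
# cross-batch bridge) with per-(gene, type) profiles, then the negative
# binomial log likelihood of the counts under the fitted means at a
# common per-gene method-of-moments dispersion. A partition that fuses
# two distinct types cannot explain both through the shared batch
# multipliers and scores visibly lower; the NB likelihood (rather than
# Poisson) keeps the score from rewarding splits of large overdispersed
# clusters.
.scorePartition <- function(y, b, cl, K, iters = 3, phiScore = 3) {
  G <- nrow(y); B <- max(b)
  s <- pmax(colSums(y), 1)
  s <- s / median(s)
  eNu <- matrix(1, G, B)
  Th <- matrix(1, G, K)
  ysumK <- vapply(seq_len(K), function(k)
    rowSums(y[, cl == k, drop = FALSE]), numeric(G))
  ysumB <- vapply(seq_len(B), function(bb)
    rowSums(y[, b == bb, drop = FALSE]), numeric(G))
  sKB <- matrix(0, K, B)
  for (i in seq_along(cl)) sKB[cl[i], b[i]] <- sKB[cl[i], b[i]] + s[i]
  for (it in seq_len(iters)) {
    for (k in seq_len(K)) {
      den <- as.numeric(eNu %*% sKB[k, ])
      Th[, k] <- (ysumK[, k] + 0.5) / (den + 0.5)
    }
    if (B >= 2) for (bb in 2:B) {
      den <- as.numeric(Th %*% sKB[, bb])
      eNu[, bb] <- (ysumB[, bb] + 0.5) / (den + 0.5)
    }
  }
  mu <- Th[, cl, drop = FALSE] * eNu[, b, drop = FALSE]
  mu <- sweep(mu, 2, s, "*")
  mu <- pmax(mu, 1e-8)
  sum(dnbinom(y, size = phiScore, mu = mu, log = TRUE))
}

# Candidate partitions, best first under the model-based score. Several
# k-means runs (the WSS optimum plus single starts) and an overclustered
# K+3 solution merged down to K by beam search over pairwise fusions:
# greedy merging is myopic here — absorbing a small type into a
# co-occurring large one can look locally cheaper than fusing the true
# twin halves of a split type, while the completed partition scores
# clearly worse.
.initCandidates <- function(data, K, nStarts = 12) {
  y <- .countsOf(data)
  N <- ncol(y)
  b <- batchIds(data); B <- max(b)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K == 1) return(list(rep(1L, N)))

  lib <- pmax(colSums(y), 1)
  sf <- lib / median(lib)
  ln <- log1p(sweep(y, 2, sf, "/"))
  # k-means runs on batch-centered log expression so that additive batch
  # effects (which dominate raw distances) do not drive the candidates
  lnc <- ln
  for (bb in seq_len(B)) {
    idx <- b == bb
    lnc[, idx] <- ln[, idx, drop = FALSE] - rowMeans(ln[, idx, drop = FALSE])
  }
  dat <- t(lnc)
  phiG <- 3
  cand <- list()
  clFine <- NULL
  if (N > K + 3) {
    km <- tryCatch(kmeans(dat, centers = K + 3, nstart = 6,
                          iter.max = 60), error = function(e) NULL)
    if (!is.null(km) && all(tabulate(km$cluster, K + 3) > 0)) {
      clFine <- as.integer(km$cluster)
      phiG <- .estimatePhiG(y, b, clFine)
    }
  }
  km <- tryCatch(kmeans(dat, centers = K, nstart = 6, iter.max = 60),
                 error = function(e) NULL)
  if (!is.null(km) && all(tabulate(km$cluster, K) > 0))
    cand[[length(cand) + 1]] <- as.integer(km$cluster)
  for (try in seq_len(nStarts)) {
    km <- tryCatch(kmeans(dat, centers = K, nstart = 1, iter.max = 60),
                   error = function(e) NULL)
    if (is.null(km) && try <= 2) {
      dat <- dat + matrix(rnorm(length(dat), 0, 1e-4), nrow(dat))
      km <- tryCatch(kmeans(dat, centers = K, nstart = 1, iter.max = 60),
                     error = function(e) NULL)
    }
    if (!is.null(km) && all(tabulate(km$cluster, K) > 0))
      cand[[length(cand) + 1]] <- as.integer(km$cluster)
  }
  if (!is.null(clFine)) {
    canon <- function(cl) as.integer(factor(cl, levels = unique(cl)))
    beam <- list(canon(clFine))
    beamWidth <- 8L
    while (max(beam[[1]]) > K) {
      pool <- list(); poolScores <- numeric(0); seen <- character(0)
      for (cl in beam) {
        Kc <- max(cl)
        for (a in seq_len(Kc - 1)) for (b2 in (a + 1):Kc) {
          clm <- cl
          clm[clm == b2] <- a
          clm[clm > b2] <- clm[clm > b2] - 1L
          clm <- canon(clm)
          key <- paste(clm, collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
          pool[[length(pool) + 1]] <- clm
          poolScores <- c(poolScores,
                          .scorePartition(y, b, clm, Kc - 1L,
                                          phiScore = phiG))
        }
      }
      keep <- order(poolScores, decreasing = TRUE)[
        seq_len(min(beamWidth, length(pool)))]
      beam <- pool[keep]
    }
    cand <- c(cand, beam)
  }
  if (!length(cand))
    stop("k-means initialization degenerate: K may exceed the number of ",
         "distinct expression profiles")
  cand <- unique(cand)
  scores <- vapply(cand, function(cl)
    .scorePartition(y, b, cl, K, phiScore = phiG), numeric(1))
  out <- cand[order(scores, decreasing = TRUE)]
  attr(out, "fine") <- clFine
  out
}

# Full sampler state for a given cell-type partition.
.buildInit <- function(data, K, hyper, variant, W) {
  y <- .countsOf(data)
  G <- nrow(y); N <- ncol(y)
  b <- batchIds(data); B <- max(b)
  K <- as.integer(K)
  W <- as.integer(W)
  lib <- pmax(colSums(y), 1)
  sf <- lib / median(lib)
  ln <- log1p(sweep(y, 2, sf, "/"))
  lnc <- ln
  for (bb in seq_len(B)) {
    idx <- b == bb
    lnc[, idx] <- ln[, idx, drop = FALSE] - rowMeans(ln[, idx, drop = FALSE])
  }

  alpha <- vapply(seq_len(G), function(g) {
    v <- y[g, ][y[g, ] > 0]
    if (length(v)) log(mean(v)) else log(0.5)
  }, numeric(1))

  # size factors by median-of-ratios against the (batch, cluster) mean
  # profile: within a cluster the type effects cancel out of the ratios,
  # so strong expression differences between types do not leak into delta
  # the way raw library-size ratios would
  first <- vapply(seq_len(B), function(bb) which(b == bb)[1], integer(1))
  delta <- numeric(N)
  for (bb in seq_len(B)) for (k in seq_len(K)) {
    idx <- which(b == bb & W == k)
    if (!length(idx)) next
    m <- rowMeans(y[, idx, drop = FALSE]) + 0.5
    delta[idx] <- log(apply((y[, idx, drop = FALSE] + 0.5) / m, 2, median))
  }
  delta <- delta - delta[first[b]]

  # empirical cluster contrasts vs cluster 1 on batch-centered expression
  lncg <- lnc + rowMeans(ln)
  cm <- vapply(seq_len(K), function(k) {
    idx <- which(W == k)
    if (length(idx)) rowMeans(pmax(expm1(lncg[, idx, drop = FALSE]), 0))
    else rep(0, G)
  }, numeric(G))
  cm <- matrix(cm, G, K)
  beta <- log(cm + 0.5) - log(cm[, 1] + 0.5)
  beta[abs(beta) < 0.5] <- 0
  beta <- pmin(pmax(beta, -5), 5)
  beta[, 1] <- 0

  bm <- vapply(seq_len(B), function(bb)
    rowMeans(expm1(ln[, b == bb, drop = FALSE])), numeric(G))
  bm <- matrix(bm, G, B)
  nu <- log(bm + 0.5) - log(bm[, 1] + 0.5)
  nu <- pmin(pmax(nu, -5), 5)
  nu[, 1] <- 0

  phi <- matrix(1, G, B)
  for (bb in seq_len(B)) {
    yy <- y[, b == bb, drop = FALSE]
    m <- rowMeans(yy)
    v <- apply(yy, 1, var)
    ph <- ifelse(v > m & m > 0, m^2 / (v - m), 10)
    phi[, bb] <- pmin(pmax(ph, 0.1), 100)
  }

  gamma0 <- rep(0, B)
  gamma1 <- rep(-0.1, B)

  xi <- hyper$xi
  pi <- t(vapply(seq_len(B), function(bb) {
    cnt <- tabulate(W[b == bb], K) + xi
    cnt / sum(cnt)
  }, numeric(K)))
  pi <- matrix(pi, B, K)

  X <- y
  Z <- matrix(0L, G, N)
  if (variant == "full") {
    zero <- which(y == 0)
    drop <- zero[runif(length(zero)) < 0.5]
    if (length(drop)) {
      mu0 <- exp(alpha + beta[, W, drop = FALSE] + nu[, b, drop = FALSE] +
                   rep(delta, each = G))
      sz0 <- phi[, b, drop = FALSE]
      X[drop] <- 1L + rnbinom(length(drop), size = sz0[drop], mu = mu0[drop])
      Z[drop] <- 1L
    }
  }

  L <- matrix(0L, G, K)
  L[, -1][abs(beta[, -1, drop = FALSE]) > 0] <- 1L

  list(alpha = alpha, beta = beta, nu = nu, delta = delta, phi = phi,
       gamma0 = gamma0, gamma1 = gamma1, pi = pi, W = W,
       X = X, Z = Z, L = L, p = 0.5,
       tau0sq = hyper$b_tau / (hyper$a_tau - 1))
}

#' Fit the batch mixture model by MCMC
#'
#' Runs \code{nChains} independent Metropolis-within-Gibbs chains with
#' distinct sub-seeds derived from \code{seed}. Each sweep updates, in
#' order: the dropout indicators and underlying counts at observed zeros
#' (drawn jointly and exactly from their full conditional), the cell-type
#' labels, compositions (conjugate Dirichlet), dropout parameters
#' (Metropolis, rejecting non-negative slopes), the log-scale effects and
#' overdispersions (random-walk Metropolis, log-scale for phi), the joint
#' spike-and-slab flips of (L, beta), and the conjugate slab probability and
#' spike variance. Proposal scales adapt toward 30 percent acceptance
#' during burn-in (Robbins-Monro) and are frozen afterwards.
#'
#' Under \code{variant = "nzf"} the model has no zero inflation: Z is fixed
#' at zero, X at Y, and the dropout updates are skipped.
#'
#' @param data a \linkS4class{BatchCounts}.
#' @param K number of cell types.
#' @param hyper hyperparameters, see \code{\link{mixHyper}}.
#' @param nIter,burnin,thin iteration counts; draws are retained after
#'   \code{burnin} at stride \code{thin}.
#' @param nChains number of independent chains (2 or more enables the
#'   potential scale reduction diagnostic).
#' @param seed master seed; chain c uses sub-seed
#'   \code{(seed + 95279 * (c - 1)) mod (2^31 - 1)}.
#' @param variant "full" or "nzf".
#' @param wFreeze warm-start length: number of initial burn-in sweeps during
#'   which the cell-type labels are held at their k-means initialization
#'   while all other blocks update, letting the parameters adapt to the
#'   initial partition before labels move. Capped at half the burn-in.
#' @param pilotSweeps,pilotCandidates before the main run, up to
#'   \code{pilotCandidates} candidate partitions are given a short
#'   frozen-label pilot run of \code{pilotSweeps} sweeps each, and the one
#'   with the best observed-data log likelihood seeds the chain (0 or 1
#'   disables piloting).
#' @return A \linkS4class{MixChains}.
#' @examples
#' \donttest{
#' d <- buildDesign("complete", B = 2, K = 2, nPerBatch = c(40, 40))
#' sim <- simulateData(simulateTruth(d, simConfig(nGenes = 60, nDE = 12)))
#' fit <- fitBatchMix(sim$data, K = 2, nIter = 200, burnin = 100)
#' }
#' @export
fitBatchMix <- function(data, K, hyper = mixHyper(), nIter = 2000,
                        burnin = 1000, thin = 1, nChains = 1, seed = 1,
                        variant = c("full", "nzf"), wFreeze = 100,
                        pilotSweeps = 60, pilotCandidates = 3) {
  variant <- match.arg(variant)
  wFreeze <- min(as.integer(wFreeze), burnin %/% 2)
  stopifnot(is(data, "BatchCounts"))
  nIter <- as.integer(nIter); burnin <- as.integer(burnin)
  thin <- as.integer(thin); nChains <- as.integer(nChains)
  if (burnin >= nIter) stop("burnin must be smaller than nIter")
  if (thin < 1 || nChains < 1) stop("thin and nChains must be >= 1")
  y <- .countsOf(data)
  b <- batchIds(data)
  bc <- as.integer(b) - 1L

  chains <- vector("list", nChains)
  for (cc in seq_len(nChains)) {
    sub <- as.integer((as.numeric(seed) + 95279 * (cc - 1)) %% 2147483647)
    set.seed(sub)
    cand <- .initCandidates(data, K, nStarts = 12)
    nPilot <- min(as.integer(pilotCandidates), length(cand))
    Wbest <- cand[[1]]
    if (nPilot > 1 && pilotSweeps > 0) {
      # short frozen-label pilot runs: adapt all parameters to each
      # candidate partition and keep the one with the best observed-data
      # log likelihood — the model itself arbitrates between candidate
      # partitions the cruder score cannot reliably rank
      ll <- rep(-Inf, nPilot)
      for (j in seq_len(nPilot)) {
        set.seed(as.integer((sub + 31 * j) %% 2147483647))
        initj <- .buildInit(data, K, hyper, variant, cand[[j]])
        ps <- as.integer(pilotSweeps)
        resj <- cpp_run_chain(y, bc, as.integer(K), hyper,
                              .initForCpp(initj), ps, ps - 1L, 1L,
                              variant == "nzf", ps)
        G <- nrow(y); B <- max(b)
        pars <- list(alpha = resj$alpha[, 1],
                     beta = matrix(resj$beta[, , 1], G, K),
                     nu = matrix(resj$nu[, , 1], G, B),
                     delta = resj$delta[, 1],
                     phi = matrix(resj$phi[, , 1], G, B),
                     gamma0 = resj$gamma0[, 1], gamma1 = resj$gamma1[, 1],
                     pi = matrix(resj$pi[, , 1], B, K))
        ll[j] <- cpp_observed_loglik(y, bc, pars$alpha, pars$beta, pars$nu,
                                     pars$delta, pars$phi, pars$gamma0,
                                     pars$gamma1, pars$pi,
                                     variant == "nzf")
      }
      Wbest <- cand[[which.max(ll)]]
    }
    set.seed(as.integer((sub + 104729) %% 2147483647))
    init <- .buildInit(data, K, hyper, variant, Wbest)
    res <- cpp_run_chain(y, bc, as.integer(K), hyper,
                         .initForCpp(init), nIter, burnin, thin,
                         variant == "nzf", wFreeze)
    res$subSeed <- sub
    chains[[cc]] <- res
  }
  new("MixChains", chains = chains, counts = y, batch = as.integer(b),
      K = as.integer(K), nIter = nIter, burnin = burnin, thin = thin,
      seed = as.integer(seed), variant = variant, hyper = hyper)
}

.initForCpp <- function(init) {
  init$W <- as.integer(init$W) - 1L
  init$X <- matrix(as.integer(init$X), nrow(init$X), ncol(init$X))
  init$Z <- matrix(as.integer(init$Z), nrow(init$Z), ncol(init$Z))
  init$L <- matrix(as.integer(init$L), nrow(init$L), ncol(init$L))
  init
}

setMethod("show", "MixChains", function(object) {
  T <- object@chains[[1]]$nStored
  cat("MixChains:", length(object@chains), "chain(s) of", T,
      "retained draws (nIter =", object@nIter, ", burnin =",
      object@burnin, ", thin =", object@thin, ")\n")
  cat("  model: K =", object@K, ", variant =", object@variant,
      ", data", nrow(object@counts), "x", ncol(object@counts), "in",
      max(object@batch), "batches\n")
  a <- object@chains[[1]]$acceptance
  cat("  acceptance (chain 1):",
      paste(sprintf("%s %.2f", names(a), unlist(a)), collapse = ", "), "\n")
})

#' Acceptance rates of the Metropolis blocks
#' @param chains a \linkS4class{MixChains}.
#' @return matrix of post-burn-in acceptance rates, chains x blocks.
#' @export
acceptanceRates <- function(chains) {
  stopifnot(is(chains, "MixChains"))
  do.call(rbind, lapply(chains@chains, function(ch) unlist(ch$acceptance)))
}
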